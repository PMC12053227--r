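#' Cell-level tumor disposition parameters
#'
#' Minimal binding-internalization-release model for a solid tumor attached
#' to the systemic model through vascular exchange only (no lymphatic
#' drainage): free ADC in the tumor extracellular space binds antigen,
#' antigen-bound ADC internalizes (antigen recycles; zero net turnover),
#' internalized ADC is degraded releasing `DAR` payload molecules, and
#' released payload exchanges between the intracellular, tumor
#' extracellular and plasma spaces.
#'
#' All defaults are ASSUMED values, not literature transcriptions: antigen
#' concentrations per immunohistochemistry grade emulate the ordering
#' TNBC < IHC1+ < IHC2+ < IHC3+ of HER2-graded breast tumors, and the
#' binding/internalization rates are typical of a high-affinity
#' internalizing antibody-antigen pair.
#'
#' @param antigen grade label (`"TNBC"`, `"IHC1+"`, `"IHC2+"`, `"IHC3+"`) or
#'   a non-negative antigen concentration in nM (extracellular space).
#' @param tumor_diameter tumor diameter, cm (volume derived as a sphere;
#'   default 2.5 cm, T2 category).
#' @param void_fraction extracellular volume fraction of the tumor.
#' @param kon_Ag,koff_Ag ADC-antigen binding rates (1/nM/h, 1/h).
#' @param k_int internalization rate of bound complex (1/h).
#' @param k_deg_tumor intracellular ADC degradation rate (1/h).
#' @param PS_adc vascular exchange for ADC (L/h).
#' @param PS_mmae vascular exchange for MMAE (L/h).
#' @param PS_cell intracellular-extracellular MMAE exchange (L/h).
#' @param Kp_tumor tumor cellular partition coefficient of MMAE.
#' @return list of class `tumor_params`.
#' @export
#' @examples
#' tumor_params("IHC3+")$antigen_nM
tumor_params <- function(antigen = "IHC2+", tumor_diameter = 2.5,
                         void_fraction = 0.3,
                         kon_Ag = 0.03, koff_Ag = 0.015, k_int = 0.05,
                         k_deg_tumor = 0.1, PS_adc = 5e-4, PS_mmae = 0.05,
                         PS_cell = 0.05, Kp_tumor = 10) {
  grades <- ihc_antigen_levels()
  if (is.character(antigen)) {
    if (!antigen %in% names(grades)) {
      .stop("unknown antigen grade '%s' (use %s or a numeric nM value)",
            antigen, paste(names(grades), collapse = ", "))
    }
    antigen_nM <- grades[[antigen]]
    grade <- antigen
  } else {
    if (!is.numeric(antigen) || antigen < 0) .stop("antigen must be >= 0 nM")
    antigen_nM <- antigen
    grade <- NA_character_
  }
  rates <- c(kon_Ag = kon_Ag, koff_Ag = koff_Ag, k_int = k_int,
             k_deg_tumor = k_deg_tumor, PS_adc = PS_adc, PS_mmae = PS_mmae,
             PS_cell = PS_cell)
  if (any(rates < 0)) .stop("tumor rates must be >= 0")
  if (tumor_diameter <= 0 || void_fraction <= 0 || void_fraction >= 1 ||
      Kp_tumor <= 0) {
    .stop("tumor_diameter, Kp_tumor must be > 0 and void_fraction in (0, 1)")
  }
  structure(list(grade = grade, antigen_nM = antigen_nM,
                 tumor_diameter = tumor_diameter,
                 void_fraction = void_fraction, kon_Ag = kon_Ag,
                 koff_Ag = koff_Ag, k_int = k_int,
                 k_deg_tumor = k_deg_tumor, PS_adc = PS_adc,
                 PS_mmae = PS_mmae, PS_cell = PS_cell,
                 Kp_tumor = Kp_tumor), class = "tumor_params")
}

#' Antigen concentrations per immunohistochemistry grade
#'
#' Assumed default antigen (HER2-like) concentrations in the tumor
#' extracellular space, strictly increasing across grades. These are
#' placeholders with a realistic ordering and magnitude, not measured
#' values.
#'
#' @return named numeric vector (nM) for TNBC, IHC1+, IHC2+, IHC3+.
#' @export
ihc_antigen_levels <- function() {
  c("TNBC" = 1, "IHC1+" = 50, "IHC2+" = 200, "IHC3+" = 1000)
}

#' Simulate ADC disposition with the tumor module attached
#'
#' Convenience wrapper over [simulate_adc()] with a `tumor_params` object.
#'
#' @inheritParams simulate_adc
#' @param tumor a [tumor_params()] list.
#' @param ... passed to [simulate_adc()].
#' @return an `adc_sim` result including tumor trajectories.
#' @export
simulate_with_tumor <- function(species, regimen, t_end,
                                tumor = tumor_params(), ...) {
  stopifnot(inherits(tumor, "tumor_params"))
  simulate_adc(species, regimen, t_end, tumor = tumor, ...)
}

#' Tumor receptor occupancy time course
#'
#' Fraction of total tumor antigen bound by ADC over time; bounded in
#' \[0, 1\] by antigen conservation (free + bound = total under the
#' zero-turnover convention).
#'
#' @param res an `adc_sim` result simulated with a tumor.
#' @return data frame with columns `time_days`, `occupancy`.
#' @export
receptor_occupancy <- function(res) {
  ctx <- res$ctx
  if (is.null(ctx$tumor)) .stop("result has no tumor module")
  ag <- ctx$tumor$ag_amount
  occ <- if (ag > 0) res$states[, ctx$ix$tbound] / ag else
    rep(0, length(res$times))
  data.frame(time_days = res$times, occupancy = pmin(pmax(occ, 0), 1))
}

#' Tumor payload concentration time courses
#'
#' @param res an `adc_sim` result simulated with a tumor.
#' @return data frame with `time_days`, intracellular and extracellular
#'   unconjugated MMAE (nM and ng/mL), bound-ADC concentration (nM).
#' @export
tumor_concentrations <- function(res) {
  ctx <- res$ctx
  if (is.null(ctx$tumor)) .stop("result has no tumor module")
  tu <- ctx$tumor; ix <- ctx$ix
  mi <- res$states[, ix$tmi] / tu$Vtcell
  me <- res$states[, ix$tme] / tu$Vtex
  data.frame(time_days = res$times,
             mmae_intracellular_nM = mi,
             mmae_extracellular_nM = me,
             mmae_intracellular_ngml = mi * ctx$MW_MMAE * 1e-3,
             mmae_extracellular_ngml = me * ctx$MW_MMAE * 1e-3,
             adc_bound_nM = res$states[, ix$tbound] / tu$Vtex)
}
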