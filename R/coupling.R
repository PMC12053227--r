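#' DAR-dependent deconjugation rate constant
#'
#' Empirical rate for nonspecific payload deconjugation as a function of the
#' current average drug-to-antibody ratio,
#' \deqn{k_{dec} = \left(\alpha - \frac{(\alpha-\beta)\,DAR^{-\tau}}
#'   {F + DAR^{-\tau}}\right)\times SF,}
#' which tends to \eqn{\alpha \cdot SF} at high DAR and to
#' \eqn{\beta \cdot SF} as DAR approaches zero (the continuous limit is used
#' at DAR = 0). Rates are per day; `SF` is the species scaling factor.
#'
#' @param DAR average drug-to-antibody ratio (>= 0); vectorized.
#' @param p deconjugation parameter list with `alpha`, `beta`, `F`, `tau`,
#'   `SF` (e.g. `default_adc_parameters(species)$deconjugation`).
#' @return deconjugation rate constant(s), 1/day.
#' @export
#' @examples
#' p <- default_adc_parameters("mouse")$deconjugation
#' kdec_of_dar(c(0, 4, 1e6), p)
kdec_of_dar <- function(DAR, p) {
  if (any(!is.finite(DAR) | DAR < 0)) .stop("DAR must be finite and >= 0")
  k <- numeric(length(DAR))
  pos <- DAR > 0
  # rewrite with DAR^tau to stay finite for small DAR:
  # (alpha - beta) * DAR^-tau / (F + DAR^-tau) = (alpha - beta) / (F * DAR^tau + 1)
  k[pos] <- p$alpha - (p$alpha - p$beta) / (p$F * DAR[pos]^p$tau + 1)
  k[!pos] <- p$beta
  k * p$SF
}

#' Time derivative of the average DAR
#'
#' \eqn{dDAR/dt = -k_{dec}(DAR) \cdot DAR} (1/day).
#'
#' @inheritParams kdec_of_dar
#' @return dDAR/dt, 1/day.
#' @export
dar_derivative <- function(DAR, p) {
  -kdec_of_dar(DAR, p) * DAR
}

#' Integrate the average-DAR decline
#'
#' High-accuracy reference integration of the DAR ordinary differential
#' equation, used by the scaling-factor fit and the fixture generator.
#'
#' @param DAR0 initial drug-to-antibody ratio.
#' @param p deconjugation parameter list (see [kdec_of_dar()]).
#' @param times_days output times (days), starting at 0 or later.
#' @param rtol,atol solver tolerances.
#' @return numeric vector of DAR values at `times_days`.
#' @export
simulate_dar <- function(DAR0, p, times_days, rtol = 1e-10, atol = 1e-12) {
  stopifnot(DAR0 > 0, !is.unsorted(times_days), all(times_days >= 0))
  tt <- times_days
  prepend <- tt[1] > 0
  if (prepend) tt <- c(0, tt)
  out <- deSolve::ode(
    y = c(DAR = DAR0), times = tt,
    func = function(t, y, parms) list(dar_derivative(max(y, 0), parms)),
    parms = p, method = "lsoda", rtol = rtol, atol = atol)
  dar <- out[, "DAR"]
  if (prepend) dar <- dar[-1]
  unname(dar)
}

#' Allometric scaling factor for the deconjugation rate
#'
#' \eqn{SF = (BW / BW_{ref})^{exponent}} with the mouse as the reference
#' species and exponent -0.25 by default. `digits` controls the reporting
#' rounding (one decimal reproduces the species values used in the model:
#' 1 mouse, 0.6 rat, 0.3 monkey, 0.1 human); `digits = NULL` returns the
#' unrounded value.
#'
#' @param body_weight body weight, kg (> 0); vectorized.
#' @param reference_weight reference body weight, kg (default mouse 0.028).
#' @param exponent allometric exponent (default -0.25).
#' @param digits rounding for reporting (default 1 decimal); `NULL` for none.
#' @return scaling factor(s), dimensionless.
#' @export
#' @examples
#' allometric_sf(c(0.28, 6.2, 70))
allometric_sf <- function(body_weight, reference_weight = 0.028,
                          exponent = -0.25, digits = 1) {
  if (any(!is.finite(body_weight) | body_weight <= 0) ||
      !is.finite(reference_weight) || reference_weight <= 0) {
    .stop("body weights must be finite and > 0")
  }
  sf <- (body_weight / reference_weight)^exponent
  if (!is.null(digits)) sf <- round(sf, digits)
  sf
}

#' Species degradation rate from the mouse value
#'
#' The conjugate's lysosomal degradation rate is the mouse-optimized naked
#' antibody rate multiplied by a species fold-change (1 for mouse and rat,
#' 3 for monkey, 4 for human) reflecting conjugation-enhanced clearance in
#' higher species.
#'
#' @param kdeg_mouse mouse degradation rate constant (1/h, > 0).
#' @param f_Kdeg fold-change (>= 1).
#' @return degradation rate constant, 1/h.
#' @export
kdeg_for_species <- function(kdeg_mouse, f_Kdeg) {
  stopifnot(kdeg_mouse > 0, f_Kdeg >= 1)
  kdeg_mouse * f_Kdeg
}

#' Hepatic clearance from intrinsic clearance
#'
#' Converts an intrinsic clearance in mL/min/kg to a whole-body unbound
#' clearance in L/h: \eqn{CL = CL_{int} \times BW \times 60/1000 \times
#' f_{up}}, applied to the unbound extracellular concentration in liver.
#'
#' @param CLint intrinsic clearance, mL/min/kg (>= 0).
#' @param fup unbound fraction in plasma (0..1).
#' @param body_weight body weight, kg.
#' @return clearance, L/h.
#' @export
#' @examples
#' hepatic_clearance_rate(2.35, 0.767, 70)
hepatic_clearance_rate <- function(CLint, fup, body_weight) {
  stopifnot(CLint >= 0, fup >= 0, fup <= 1, body_weight > 0)
  CLint * body_weight * 60 / 1000 * fup
}

#' Assemble reported analyte concentrations
#'
#' Converts molar plasma concentrations to the units in which the four ADC
#' analytes are conventionally reported: total antibody in ug/mL,
#' conjugated MMAE (`DAR x` antibody, molar) and unconjugated MMAE in
#' ng/mL.
#'
#' @param mab_nM total antibody plasma concentration, nM; vectorized.
#' @param DAR average drug-to-antibody ratio; vectorized.
#' @param mmae_nM unconjugated MMAE plasma concentration, nM; vectorized.
#' @param MW_mAb,MW_MMAE molecular weights, g/mol.
#' @return data frame with columns `total_mab_ugml`, `conjugated_mmae_ngml`,
#'   `unconjugated_mmae_ngml`.
#' @export
analyte_assembly <- function(mab_nM, DAR, mmae_nM,
                             MW_mAb = 150000, MW_MMAE = 717.98) {
  data.frame(
    total_mab_ugml = mab_nM * MW_mAb * 1e-6,
    conjugated_mmae_ngml = DAR * mab_nM * MW_MMAE * 1e-3,
    unconjugated_mmae_ngml = mmae_nM * MW_MMAE * 1e-3
  )
}

#' Deconjugation release fluxes from an antibody state snapshot
#'
#' For every antibody-containing pool (tissue vascular, interstitial and
#' endosomal sub-compartments, plus the blood and lymph-node pools) the
#' payload molar source is `kdec x DAR x` (antibody molar amount). Released
#' payload enters the payload model's pool of the same tissue (endosomal
#' release is mapped to the lumped extracellular pool); blood and lymph-node
#' release enters the plasma pool.
#'
#' @param mab_amounts named list with `tissue` (a numeric matrix or data
#'   frame with columns `vascular`, `endosomal_unbound`, `endosomal_bound`,
#'   `interstitial`, rows = tissues, nmol), `blood` and `lymph_node`
#'   (scalars, nmol).
#' @param DAR average drug-to-antibody ratio.
#' @param p deconjugation parameter list (see [kdec_of_dar()]).
#' @return list with `tissue` (named vector of payload source rates into
#'   each tissue's extracellular pool, nmol/day), `plasma` (rate into the
#'   blood plasma pool, nmol/day) and `total`.
#' @export
deconjugation_release_fluxes <- function(mab_amounts, DAR, p) {
  kd <- kdec_of_dar(DAR, p)
  tis <- as.matrix(as.data.frame(mab_amounts$tissue)[
    , c("vascular", "endosomal_unbound", "endosomal_bound", "interstitial")])
  per_tissue <- kd * DAR * rowSums(tis)
  plasma <- kd * DAR * (mab_amounts$blood + mab_amounts$lymph_node)
  list(tissue = per_tissue, plasma = plasma,
       total = sum(per_tissue) + plasma)
}

#' Degradation-driven payload release flux
#'
#' Each antibody degraded in the endosomal space releases a number of
#' payload molecules equal to the current average DAR; the flux is
#' `kdeg x amount x DAR`, delivered to the same tissue's cellular pool.
#'
#' @param endosomal_unbound_mab_amount FcRn-unbound endosomal antibody
#'   amount (nmol, >= 0); vectorized.
#' @param kdeg degradation rate constant (1/h, >= 0).
#' @param DAR average drug-to-antibody ratio (>= 0).
#' @return payload molar release rate(s), nmol/h.
#' @export
degradation_release_flux <- function(endosomal_unbound_mab_amount, kdeg, DAR) {
  stopifnot(all(endosomal_unbound_mab_amount >= 0), kdeg >= 0, DAR >= 0)
  kdeg * endosomal_unbound_mab_amount * DAR
}
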