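# State layout and right-hand side of the coupled antibody + payload + DAR
# system. Internal unit system: amounts nmol, concentrations nM, volumes L,
# time h. Deconjugation parameters are per day and converted at use.
#
# Layout (n = number of perfused tissues):
#   mAb:     vascular, endosomal unbound, endosomal bound, interstitial,
#            free FcRn (per tissue); blood pool; lymph-node pool;
#            cumulative degraded (ledger)
#   payload: extracellular (lumped plasma+endosomal+interstitial),
#            blood cell, cellular (per tissue); blood plasma; blood cells;
#            cumulative hepatic elimination (ledger)
#   conj:    total conjugated-payload amount (defines DAR by ratio to the
#            total antibody amount)
#   ledgers: deconjugation release per tissue; deconjugation release in
#            plasma (blood + lymph node); degradation release per tissue;
#            tumor release
#   tumor:   free / antigen-bound / internalized ADC, free antigen,
#            intracellular and extracellular MMAE (optional)

.state_layout <- function(n, tumor = FALSE) {
  ix <- list(
    mv   = 1:n,
    meu  = n + 1:n,
    meb  = 2L * n + 1:n,
    mi   = 3L * n + 1:n,
    fcr  = 4L * n + 1:n,
    mb   = 5L * n + 1L,
    mln  = 5L * n + 2L,
    mdeg = 5L * n + 3L,
    pec  = 5L * n + 3L + 1:n,
    pbc  = 6L * n + 3L + 1:n,
    pcl  = 7L * n + 3L + 1:n,
    ppb  = 8L * n + 4L,
    pbb  = 8L * n + 5L,
    pel  = 8L * n + 6L,
    conj = 8L * n + 7L,
    ldec = 8L * n + 7L + 1:n,
    ldecp = 9L * n + 8L,
    ldeg = 9L * n + 8L + 1:n,
    ltum = 10L * n + 9L
  )
  if (tumor) {
    b <- 10L * n + 9L
    ix <- c(ix, list(tfree = b + 1L, tbound = b + 2L, tagf = b + 3L,
                     tint = b + 4L, tmi = b + 5L, tme = b + 6L))
  }
  ix
}

#' Build a simulation context
#'
#' Pre-computes the index map, volumes, flows and rate constants consumed by
#' the right-hand side [adc_rhs()]. Mostly useful for direct derivative
#' evaluation in tests; [simulate_adc()] builds its own context.
#'
#' @param phys a validated [species_physiology][load_species_physiology] object.
#' @param params an [adc_parameters][default_adc_parameters] list.
#' @param tumor optional [tumor_params()] list.
#' @param deliver which release-source groups deliver payload into the
#'   payload model, any subset of `"plasma_deconjugation"`,
#'   `"tissue_deconjugation"`, `"tissue_degradation"`, `"tumor"` (default
#'   all); removing a group leaves the conjugated pool's dynamics unchanged
#'   but masks delivery, which is how [plasma_source_attribution()]
#'   decomposes plasma payload exposure.
#' @return a list of class `adc_context`.
#' @export
build_context <- function(phys, params, tumor = NULL,
                          deliver = c("plasma_deconjugation",
                                      "tissue_deconjugation",
                                      "tissue_degradation", "tumor")) {
  stopifnot(inherits(phys, "species_physiology"))
  validate_adc_params(params)
  tab <- phys$tissues
  per <- tab[match(adc_tissues, tab$name), ]
  n <- nrow(per)
  blood <- tab[tab$name == "blood", ]
  ln <- tab[tab$name == "lymph_node", ]
  if (any(per$V_plasma <= 0 | per$V_bloodcell <= 0 | per$V_endosomal <= 0 |
          per$V_interstitial <= 0 | per$V_cellular <= 0 | per$Q_plasma <= 0)) {
    .stop("perfused tissues need strictly positive volumes and flows")
  }
  kp <- params$payload$kp_table
  kpt <- kp[match(adc_tissues, kp$tissue), ]
  ps_s <- params$payload$ps_scaling %||% "none"
  ps_fac <- if (identical(ps_s, "none")) 1 else
    (phys$body_weight / 0.028)^as.numeric(ps_s)
  bw <- phys$body_weight
  m <- params$mab
  # direct product (not kdeg_for_species) so closed-system experiments with
  # kdeg_base = 0 remain expressible
  kdeg_adc <- m$kdeg_base * params$coupling$f_Kdeg

  ctx <- list(
    n = n, species = phys$species, body_weight = bw,
    ix = .state_layout(n, tumor = !is.null(tumor)),
    tissue_names = per$name,
    i_lung = match("lung", per$name),
    i_liver = match("liver", per$name),
    i_spl = match(adc_splanchnic, per$name),
    Vp = per$V_plasma, Vbc = per$V_bloodcell, Ve = per$V_endosomal,
    Vi = per$V_interstitial, Vc = per$V_cellular,
    Vec = per$V_plasma + per$V_endosomal + per$V_interstitial,
    Vt = per$V_plasma + per$V_bloodcell + per$V_endosomal +
      per$V_interstitial + per$V_cellular,
    Q = per$Q_plasma, L = per$L_lymph,
    sv = per$sigma_v, si = per$sigma_i,
    Vbp = blood$V_plasma, Vbcb = blood$V_bloodcell, Vln = ln$V_plasma,
    Ltot = sum(per$L_lymph),
    kon = m$kon_FcRn, koff = m$koff_FcRn, FR = m$FR,
    CLupVe = m$CL_up * per$V_endosomal,
    kdeg = kdeg_adc,
    fcrn_amount = phys$FcRn_total * per$V_endosomal,
    KpBC = params$payload$Kp_BC,
    Kp = kpt$Kp,
    PScl = kpt$PS_cell * ps_fac,
    PSbc = kpt$PS_BC * ps_fac,
    PSbc_blood = kp$PS_BC[match("blood", kp$tissue)] * ps_fac,
    CLhep = hepatic_clearance_rate(params$payload$CLint, params$payload$fup, bw),
    dec = params$deconjugation,
    DAR0 = params$coupling$DAR0,
    MW_mAb = params$coupling$MW_mAb, MW_MMAE = params$coupling$MW_MMAE,
    del_pdec = "plasma_deconjugation" %in% deliver,
    del_tdec = "tissue_deconjugation" %in% deliver,
    del_tdeg = "tissue_degradation" %in% deliver,
    del_tum = "tumor" %in% deliver,
    tumor = NULL
  )
  ctx$i_plain <- setdiff(seq_len(n), c(ctx$i_lung, ctx$i_liver, ctx$i_spl))
  ctx$Qlung_out <- sum(ctx$Q[-ctx$i_lung])
  if (!is.null(tumor)) {
    tu <- tumor
    vtum <- 4 / 3 * pi * (tu$tumor_diameter / 2)^3 / 1000  # cm^3 -> L
    ctx$tumor <- list(
      Vtex = tu$void_fraction * vtum,
      Vtcell = (1 - tu$void_fraction) * vtum,
      ag_amount = tu$antigen_nM * tu$void_fraction * vtum,
      konAg = tu$kon_Ag, koffAg = tu$koff_Ag, kint = tu$k_int,
      kdegT = tu$k_deg_tumor, PS_adc = tu$PS_adc, PS_mmae = tu$PS_mmae,
      PS_cell = tu$PS_cell, Kp = tu$Kp_tumor
    )
  }
  ctx$n_state <- max(unlist(ctx$ix))
  class(ctx) <- "adc_context"
  ctx
}

#' Initial (pre-dose) state vector
#'
#' All drug amounts zero; free FcRn at its endosomal total; tumor antigen
#' (when present) entirely free.
#'
#' @param ctx an [adc_context][build_context].
#' @return named numeric state vector (amounts, nmol).
#' @export
initial_state <- function(ctx) {
  ix <- ctx$ix
  y <- numeric(ctx$n_state)
  nm <- character(ctx$n_state)
  tn <- ctx$tissue_names
  for (f in c("mv", "meu", "meb", "mi", "fcr", "pec", "pbc", "pcl",
              "ldec", "ldeg")) nm[ix[[f]]] <- paste0(f, ".", tn)
  for (f in c("mb", "mln", "mdeg", "ppb", "pbb", "pel", "conj", "ldecp",
              "ltum", "tfree", "tbound", "tagf", "tint", "tmi", "tme")) {
    if (!is.null(ix[[f]])) nm[ix[[f]]] <- f
  }
  names(y) <- nm
  y[ix$fcr] <- ctx$fcrn_amount
  if (!is.null(ctx$tumor)) y[ix$tagf] <- ctx$tumor$ag_amount
  y
}

# raw right-hand side used by the solver (no input validation)
.rhs <- function(t, y, ctx) {
  ix <- ctx$ix
  n <- ctx$n
  il <- ctx$i_lung; ih <- ctx$i_liver; is <- ctx$i_spl

  # ---- antibody ----
  Cv <- y[ix$mv] / ctx$Vp
  Ceu <- y[ix$meu] / ctx$Ve
  Ceb <- y[ix$meb] / ctx$Ve
  Ci <- y[ix$mi] / ctx$Vi
  Ff <- y[ix$fcr] / ctx$Ve
  Cb <- y[ix$mb] / ctx$Vbp
  Cln <- y[ix$mln] / ctx$Vln

  art <- rep.int(Cv[il], n); art[il] <- Cb
  infl <- ctx$Q * art
  spl_out <- (ctx$Q[is] - ctx$L[is]) * Cv[is]
  infl[ih] <- infl[ih] + sum(spl_out)
  outc <- ctx$Q - ctx$L
  outc[ih] <- ctx$Q[ih] + sum(ctx$Q[is] - ctx$L[is]) - ctx$L[ih]
  outfl <- outc * Cv
  outfl[il] <- ctx$Qlung_out * Cv[il]

  ly_in <- ctx$L * (1 - ctx$sv) * Cv
  ly_out <- ctx$L * (1 - ctx$si) * Ci
  up_v <- ctx$CLupVe * Cv
  up_i <- ctx$CLupVe * Ci
  bind <- ctx$kon * Ceu * Ff * ctx$Ve
  unb <- ctx$koff * y[ix$meb]
  recyc <- ctx$CLupVe * Ceb
  deg <- ctx$kdeg * y[ix$meu]

  dy <- numeric(ctx$n_state)
  dy[ix$mv] <- infl - outfl - ly_in - up_v + ctx$FR * recyc
  dy[ix$mi] <- ly_in - ly_out - up_i + (1 - ctx$FR) * recyc
  dy[ix$meu] <- up_v + up_i - bind + unb - deg
  dy[ix$meb] <- bind - unb - recyc
  dy[ix$fcr] <- -bind + unb + recyc
  dy[ix$mb] <- sum(outfl[ctx$i_plain]) + outfl[ih] + ctx$Ltot * Cln -
    ctx$Q[il] * Cb
  dy[ix$mln] <- sum(ly_out) - ctx$Ltot * Cln
  dy[ix$mdeg] <- sum(deg)

  # ---- DAR from the conjugated-payload / antibody amount ratio ----
  amab <- sum(y[ix$mv]) + sum(y[ix$meu]) + sum(y[ix$meb]) + sum(y[ix$mi]) +
    y[ix$mb] + y[ix$mln]
  if (!is.null(ctx$tumor)) {
    amab <- amab + y[ix$tfree] + y[ix$tbound] + y[ix$tint]
  }
  DAR <- if (amab > 1e-12) max(y[ix$conj], 0) / amab else 0
  kdec_h <- kdec_of_dar(DAR, ctx$dec) / .day_h

  rel_dec_t <- kdec_h * DAR * (y[ix$mv] + y[ix$meu] + y[ix$meb] + y[ix$mi])
  rel_dec_p <- kdec_h * DAR * (y[ix$mb] + y[ix$mln])
  rel_deg_t <- deg * DAR
  dconj <- -(sum(rel_dec_t) + rel_dec_p + sum(rel_deg_t))

  # ---- payload ----
  Cec <- y[ix$pec] / ctx$Vec
  Cbc <- y[ix$pbc] / ctx$Vbc
  Ccl <- y[ix$pcl] / ctx$Vc
  Cpb <- y[ix$ppb] / ctx$Vbp
  Cbb <- y[ix$pbb] / ctx$Vbcb

  artp <- rep.int(Cec[il], n); artp[il] <- Cpb
  inflp <- ctx$Q * artp
  inflp[ih] <- inflp[ih] + sum(ctx$Q[is] * Cec[is])
  outcp <- ctx$Q
  outcp[ih] <- ctx$Q[ih] + sum(ctx$Q[is])
  outflp <- outcp * Cec
  outflp[il] <- ctx$Qlung_out * Cec[il]

  exbc <- ctx$PSbc * (Cec - Cbc / ctx$KpBC)
  excl <- ctx$PScl * (Cec - Ccl / ctx$Kp)
  exbb <- ctx$PSbc_blood * (Cpb - Cbb / ctx$KpBC)
  elim <- ctx$CLhep * Cec[ih]

  dy[ix$pec] <- inflp - outflp - exbc - excl
  if (ctx$del_tdec) dy[ix$pec] <- dy[ix$pec] + rel_dec_t
  dy[ix$pec][ih] <- dy[ix$pec][ih] - elim
  dy[ix$pbc] <- exbc
  dy[ix$pcl] <- excl
  if (ctx$del_tdeg) dy[ix$pcl] <- dy[ix$pcl] + rel_deg_t
  dy[ix$ppb] <- sum(outflp[ctx$i_plain]) + outflp[ih] - ctx$Q[il] * Cpb - exbb
  if (ctx$del_pdec) dy[ix$ppb] <- dy[ix$ppb] + rel_dec_p
  dy[ix$pbb] <- exbb
  dy[ix$pel] <- elim

  dy[ix$ldec] <- rel_dec_t
  dy[ix$ldecp] <- rel_dec_p
  dy[ix$ldeg] <- rel_deg_t

  # ---- tumor ----
  if (!is.null(ctx$tumor)) {
    tu <- ctx$tumor
    Ctf <- y[ix$tfree] / tu$Vtex
    flux_adc <- tu$PS_adc * (Cb - Ctf)
    bindT <- tu$konAg * Ctf * y[ix$tagf]
    unbT <- tu$koffAg * y[ix$tbound]
    intT <- tu$kint * y[ix$tbound]
    degT <- tu$kdegT * y[ix$tint]
    rel_tu_ex <- kdec_h * DAR * (y[ix$tfree] + y[ix$tbound])
    rel_tu_in <- kdec_h * DAR * y[ix$tint] + degT * DAR
    dy[ix$tfree] <- flux_adc - bindT + unbT
    dy[ix$tbound] <- bindT - unbT - intT
    dy[ix$tagf] <- -bindT + unbT + intT  # antigen recycled on internalization
    dy[ix$tint] <- intT - degT
    Cmi <- y[ix$tmi] / tu$Vtcell
    Cme <- y[ix$tme] / tu$Vtex
    ex_cell <- tu$PS_cell * (Cme - Cmi / tu$Kp)
    ex_pl <- tu$PS_mmae * (Cpb - Cme)
    dy[ix$tmi] <- ex_cell
    dy[ix$tme] <- -ex_cell + ex_pl
    if (ctx$del_tum) {
      dy[ix$tmi] <- dy[ix$tmi] + rel_tu_in
      dy[ix$tme] <- dy[ix$tme] + rel_tu_ex
    }
    dy[ix$ppb] <- dy[ix$ppb] - ex_pl
    dy[ix$mb] <- dy[ix$mb] - flux_adc
    dy[ix$mdeg] <- dy[ix$mdeg] + degT
    dy[ix$ltum] <- rel_tu_in + rel_tu_ex
    dconj <- dconj - rel_tu_ex - rel_tu_in
  }
  dy[ix$conj] <- dconj
  list(dy)
}

#' Evaluate the coupled model right-hand side
#'
#' Direct derivative evaluation for a given state, with domain validation
#' (negative amounts are rejected). The same function, without validation,
#' drives the solver inside [simulate_adc()].
#'
#' @param t time (h); the system is autonomous, so `t` only matters for
#'   solver bookkeeping.
#' @param y named state vector as produced by [initial_state()] (nmol).
#' @param ctx an [adc_context][build_context].
#' @return list whose first element is the derivative vector (nmol/h).
#' @export
adc_rhs <- function(t, y, ctx) {
  if (length(y) != ctx$n_state) {
    .stop("state vector has length %d, expected %d", length(y), ctx$n_state)
  }
  if (any(y < 0)) .stop("negative state entries are outside the model domain")
  .rhs(t, y, ctx)
}
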