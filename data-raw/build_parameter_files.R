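# Builds the packaged species physiology tables, the MMAE Kp/PS table and the
# per-species ADC parameter files under inst/extdata/.
#
# The supplementary physiology tables of the source platform models are not
# redistributable here, so organ volumes and plasma flows are synthesized from
# standard physiology compilations: organ masses as fractions of body weight
# (density 1 g/mL), plasma flows as fractions of cardiac output, cardiac
# output (blood) = 14.1 * BW^0.75 L/h, hematocrit 0.45. The fractional
# composition is held identical across species. Files carry a "synthetic"
# provenance note in their headers.
#
# Run from the package root:  Rscript data-raw/build_parameter_files.R

fmt <- function(x) sprintf("%.15g", x)

species <- list(
  mouse  = list(bw = 0.028, fcrn = 29900),
  rat    = list(bw = 0.28,  fcrn = 91400),
  monkey = list(bw = 6.2,   fcrn = 30000),
  human  = list(bw = 70,    fcrn = 33800)
)
hct <- 0.45
lymph_frac <- 0.002   # lymph flow as fraction of tissue plasma flow
endo_frac  <- 0.005   # endosomal space as fraction of tissue volume

# name, frac of BW, frac of plasma cardiac output (liver = hepatic artery),
# vascular blood fraction of tissue volume, interstitial fraction,
# sigma_v (vascular reflection)
tis <- data.frame(
  name  = c("lung","heart","kidney","muscle","skin","liver","brain","fat",
            "thymus","bone","small_intestine","large_intestine","spleen",
            "pancreas","other"),
  f_bw  = c(0.008, 0.005, 0.0044, 0.40, 0.037, 0.026, 0.020, 0.100,
            0.0009, 0.080, 0.009, 0.006, 0.0026, 0.0014, 0.190),
  f_q   = c(1.000, 0.040, 0.170, 0.170, 0.058, 0.065, 0.110, 0.050,
            0.0015, 0.050, 0.100, 0.040, 0.020, 0.010, 0.1155),
  f_vas = c(0.15, 0.06, 0.08, 0.02, 0.02, 0.12, 0.03, 0.01,
            0.03, 0.03, 0.02, 0.02, 0.20, 0.05, 0.03),
  f_int = c(0.19, 0.10, 0.15, 0.13, 0.30, 0.165, 0.05, 0.135,
            0.15, 0.10, 0.19, 0.19, 0.15, 0.12, 0.15),
  sig_v = c(0.95, 0.95, 0.90, 0.95, 0.95, 0.85, 0.99, 0.95,
            0.90, 0.85, 0.90, 0.90, 0.85, 0.90, 0.95)
)
stopifnot(abs(sum(tis$f_q[-1]) - 1) < 1e-12)  # organ flows sum to lung flow

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)

for (sp in names(species)) {
  bw <- species[[sp]]$bw
  co_plasma <- 14.1 * bw^0.75 * (1 - hct)   # L/h
  vt  <- tis$f_bw * bw                      # L (density 1)
  vp  <- tis$f_vas * (1 - hct) * vt
  vbc <- tis$f_vas * hct * vt
  ve  <- endo_frac * vt
  vi  <- tis$f_int * vt
  vc  <- pmax(vt - vp - vbc - ve - vi, 0.01 * vt)
  q   <- tis$f_q * co_plasma
  l   <- lymph_frac * q
  rows <- data.frame(
    name = tis$name, V_plasma = vp, V_bloodcell = vbc, V_endosomal = ve,
    V_interstitial = vi, V_cellular = vc, Q_plasma = q, L_lymph = l,
    sigma_v = tis$sig_v, sigma_i = 0.2
  )
  # blood: central (arterial + venous) plasma and blood-cell pools
  v_plasma_central <- 0.0231 * bw
  rows <- rbind(rows, data.frame(
    name = "blood", V_plasma = v_plasma_central,
    V_bloodcell = v_plasma_central * hct / (1 - hct),
    V_endosomal = 0, V_interstitial = 0, V_cellular = 0,
    Q_plasma = co_plasma, L_lymph = 0, sigma_v = 0, sigma_i = 0))
  # lymph node: single well-mixed pool draining total lymph to blood
  rows <- rbind(rows, data.frame(
    name = "lymph_node", V_plasma = 0.002 * bw, V_bloodcell = 0,
    V_endosomal = 0, V_interstitial = 0, V_cellular = 0,
    Q_plasma = sum(l), L_lymph = 0, sigma_v = 0, sigma_i = 0))

  path <- file.path("inst/extdata", paste0("physiology_", sp, ".csv"))
  hdr <- c(
    paste0("# Species physiology for the whole-body ADC PBPK model: ", sp),
    "# SYNTHETIC parameterization: organ volumes and plasma flows assembled",
    "# from standard physiology compilations (fraction-of-body-weight organ",
    "# masses, fraction-of-cardiac-output plasma flows, cardiac output",
    "# 14.1*BW^0.75 L/h blood); not transcribed from any single source.",
    "# Liver Q_plasma is hepatic-artery flow; splanchnic organs (spleen,",
    "# small/large intestine, pancreas) drain into the liver inflow.",
    "# Lymph flow = 0.2% of tissue plasma flow. Units: volumes L, flows L/h.",
    paste0("# species: ", sp),
    paste0("# body_weight_kg: ", fmt(bw)),
    paste0("# hematocrit: ", fmt(hct)),
    paste0("# fcrn_nM: ", fmt(species[[sp]]$fcrn)),
    paste0("# lymph_fraction: ", fmt(lymph_frac))
  )
  con <- file(path, "w")
  writeLines(hdr, con)
  writeLines(paste(names(rows), collapse = ","), con)
  apply(rows, 1, function(r) {
    writeLines(paste(c(r[1], fmt(as.numeric(r[-1]))), collapse = ","), con)
  })
  close(con)
  message("wrote ", path)
}

# ---- MMAE tissue partition coefficients and permeability products ---------
# ASSUMED DEFAULTS, not paper values: the source Kp table (mouse
# biodistribution-derived) is not printed in the paper. Magnitudes chosen for
# a lipophilic, extensively distributed tubulin inhibitor. PS values are
# species-independent by default (the paper's selected configuration).
hu <- species$human$bw
vt_h <- tis$f_bw * hu
vc_h <- pmax(vt_h - tis$f_vas * (1 - hct) * vt_h - tis$f_vas * hct * vt_h -
               endo_frac * vt_h - tis$f_int * vt_h, 0.01 * vt_h)
vbc_h <- tis$f_vas * hct * vt_h
kp <- data.frame(
  tissue = tis$name,
  Kp = c(10, 8, 15, 5, 8, 30, 0.5, 10, 8, 5, 15, 15, 20, 10, 8),
  PS_cell = 0.05 * vc_h,
  PS_BC = 5 * vbc_h
)
kp <- rbind(kp, data.frame(tissue = "blood", Kp = NA,
                           PS_cell = 0, PS_BC = 5 * 0.0231 * hu * hct / (1 - hct)))
path <- "inst/extdata/mmae_kp_ps.csv"
con <- file(path, "w")
writeLines(c(
  "# MMAE tissue-to-plasma partition coefficients (Kp) and permeability-",
  "# surface-area products (PS, L/h) for cellular and blood-cell exchange.",
  "# SYNTHETIC assumed defaults (the mouse-biodistribution-derived table is",
  "# not printed in the source literature); species-independent by default.",
  "# Kp on the blood row is unused (blood-cell partitioning uses Kp_BC from",
  "# the species parameter file)."), con)
writeLines(paste(names(kp), collapse = ","), con)
apply(kp, 1, function(r) writeLines(paste(c(r[1], fmt(as.numeric(r[-1]))),
                                          collapse = ","), con))
close(con)
message("wrote ", path)

# ---- per-species ADC parameter files --------------------------------------
# kon/koff/fup/Kp_BC/CLint/f_Kdeg/SF as printed in the source Table 1;
# CL_up, FR, kdeg_base, DAR0 and molecular weights are platform-style
# defaults documented in the package.
p <- list(
  mouse  = list(kon = 0.0806, koff = 6.55, fup = 0.200, kpbc = 5.46,
                clint = 67.7, fkdeg = 1, sf = 1.0),
  rat    = list(kon = 0.800, koff = 144, fup = 0.875, kpbc = 4.00,
                clint = 16.4, fkdeg = 1, sf = 0.6),
  monkey = list(kon = 0.792, koff = 46.8, fup = 0.180, kpbc = 3.00,
                clint = 33.6, fkdeg = 3, sf = 0.3),
  human  = list(kon = 0.559, koff = 23.9, fup = 0.767, kpbc = 1.34,
                clint = 2.35, fkdeg = 4, sf = 0.1)
)
for (sp in names(p)) {
  x <- p[[sp]]
  path <- file.path("inst/extdata", paste0("adc_params_", sp, ".yaml"))
  writeLines(c(
    paste0("# ADC parameter set (", sp, ") for the MMAE ADC PBPK model."),
    "# mab: FcRn binding kinetics (1/nM/h, 1/h), pinocytosis rate per unit",
    "#   endosomal volume (1/h), recycled fraction, lysosomal degradation of",
    "#   FcRn-unbound antibody (1/h, naked-mAb base; multiplied by",
    "#   coupling$f_Kdeg for the conjugate).",
    "# payload: unbound plasma fraction, blood-cell partition, hepatic",
    "#   intrinsic clearance (mL/min/kg).",
    "# deconjugation: empirical DAR-dependent rate (1/day) and species",
    "#   scaling factor.",
    "mab:",
    paste0("  kon_FcRn: ", x$kon),
    paste0("  koff_FcRn: ", x$koff),
    "  CL_up: 0.55",
    "  FR: 0.715",
    "  kdeg_base: 30",
    "payload:",
    paste0("  fup: ", x$fup),
    paste0("  Kp_BC: ", x$kpbc),
    paste0("  CLint: ", x$clint),
    "  ps_scaling: none",
    "deconjugation:",
    "  alpha: 0.0806",
    "  beta: 0.0102",
    "  F: 0.282",
    "  tau: 5.68",
    paste0("  SF: ", x$sf),
    "coupling:",
    "  DAR0: 4",
    paste0("  f_Kdeg: ", x$fkdeg),
    "  MW_mAb: 150000",
    "  MW_MMAE: 717.98"
  ), path)
  message("wrote ", path)
}
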