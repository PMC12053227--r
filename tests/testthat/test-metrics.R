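test_that("dose normalization scales linearly and round-trips", {
  rec <- data.frame(dose_mgkg = c(5, 10, 2), conc = c(10, 30, 4))
  out <- dose_normalize(rec, 10)
  expect_equal(out$conc, c(20, 30, 20))
  expect_equal(out$dose_mgkg, rep(10, 3))
  expect_equal(dose_normalize(out, 10), out)            # idempotent at target
  back <- dose_normalize(out, 5)
  expect_equal(dose_normalize(back, 10)$conc, out$conc) # invertible
  rec$dose_mgkg[2] <- 0
  expect_error(dose_normalize(rec, 10), "positive dose")
})

test_that("pooling averages within nominal-time bins, order-invariantly", {
  rec <- data.frame(time_day = c(1, 1.02, 7, 7.1, 21),
                    conc = c(10, 20, 5, 7, 2))
  pooled <- pool_profiles(rec)
  expect_equal(pooled$conc, c(15, 6, 2))
  expect_equal(pooled$n, c(2L, 2L, 1L))
  perm <- pool_profiles(rec[c(4, 1, 5, 3, 2), ])
  expect_equal(perm$conc, pooled$conc)
  expect_equal(pool_profiles(rec[5, , drop = FALSE])$conc, 2)
  expect_error(pool_profiles(rec[0, ]), "no records")
})

test_that("the observed DAR profile is the molar analyte ratio", {
  conj <- data.frame(time_day = 1, conc = 400)
  mab <- data.frame(time_day = 1, conc = 100)
  prof <- observed_dar_profile(conj, mab, conj_unit = "nM", mab_unit = "nM")
  expect_equal(prof$dar, 4)
  prof0 <- observed_dar_profile(
    data.frame(time_day = 1, conc = 0), mab,
    conj_unit = "nM", mab_unit = "nM")
  expect_equal(prof0$dar, 0)
  expect_warning(
    out <- observed_dar_profile(conj, data.frame(time_day = 1, conc = 0),
                                conj_unit = "nM", mab_unit = "nM"),
    "zero antibody")
  expect_equal(nrow(out), 0L)
  expect_error(conc_to_nM(1, "furlongs", 100), "unknown concentration unit")
})

test_that("trapezoidal AUC matches closed forms", {
  tt <- seq(0, 5, by = 0.01)
  expect_equal(auc_trapezoid(c(0, 3), c(2, 2)), 6)
  expect_equal(auc_trapezoid(tt, exp(-tt)), 1 - exp(-5), tolerance = 1e-4)
  expect_error(auc_trapezoid(1, 1), "two points")
  expect_error(auc_trapezoid(c(2, 1), c(1, 1)), "increasing")
})

test_that("sparse AUC reduces to the trapezoid with one observation per bin", {
  tt <- c(0.25, 1, 3, 7)
  cc <- c(10, 8, 4, 1)
  sp <- auc_sparse(data.frame(time_day = tt, conc = cc))
  expect_equal(sp$auc, auc_trapezoid(tt, cc))
  expect_false(sp$se_defined)
  expect_true(is.na(sp$se))
  # duplicated identical observations: same AUC, zero SE
  rec2 <- data.frame(time_day = rep(tt, each = 2), conc = rep(cc, each = 2))
  sp2 <- auc_sparse(rec2)
  expect_equal(sp2$auc, sp$auc)
  expect_true(sp2$se_defined)
  expect_equal(sp2$se, 0)
  expect_error(auc_sparse(data.frame(time_day = c(1, 1.001),
                                     conc = c(1, 2))), "two time bins")
})

test_that("percent prediction error has the two-fold boundary values and antisymmetry", {
  expect_equal(percent_pe(1, 1), 0)
  expect_equal(percent_pe(2, 1), 100)
  expect_equal(percent_pe(1, 2), -100)
  set.seed(7)
  a <- stats::runif(50, 0.1, 50); b <- stats::runif(50, 0.1, 50)
  expect_equal(percent_pe(a, b), -percent_pe(b, a))
  expect_error(percent_pe(0, 1), "> 0")
})

test_that("the scaling-factor fit recovers known values from noise-free profiles", {
  fixed <- default_adc_parameters("mouse")$deconjugation[
    c("alpha", "beta", "F", "tau")]
  tt <- c(0.25, 1, 3, 7, 14, 21, 35, 56)
  for (sf in c(0.3, 1.0)) {
    dar <- simulate_dar(4, c(fixed, list(SF = sf)), tt)
    fit <- fit_sf(tt, dar, fixed, DAR0 = 4)
    expect_true(fit$converged)
    expect_lt(abs(fit$sf - sf) / sf, 0.005)
  }
  expect_error(fit_sf(c(1, 2), c(3, 2), fixed, 4), "at least 3")
  expect_error(fit_sf(tt, rep(5, 8), fixed, 4), "DAR0")
})

test_that("the scaling-factor fit tolerates multiplicative noise", {
  fixed <- default_adc_parameters("mouse")$deconjugation[
    c("alpha", "beta", "F", "tau")]
  tt <- c(0.25, 1, 3, 7, 14, 21, 35, 56)
  dar_true <- simulate_dar(4, c(fixed, list(SF = 0.6)), tt)
  set.seed(11)
  hits <- vapply(1:50, function(i) {
    noisy <- dar_true * exp(rnorm(8, 0, 0.1))
    fit <- fit_sf(tt, pmin(noisy, 4), fixed, DAR0 = 4)
    abs(fit$sf - 0.6) / 0.6 < 0.2
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("Kp sensitivity has the expected sign and preserves mass balance", {
  reg <- build_regimen("single", 5)
  sens <- kp_sensitivity("rat", reg, t_end = 14, tissues = "liver",
                         dt_out = 0.5)
  up <- sens[sens$direction == "+", ]
  expect_gt(up$pct_change_tissue_auc, 0)   # higher Kp, more tissue payload
  down <- sens[sens$direction == "-", ]
  expect_lt(down$pct_change_tissue_auc, 0)
  sens0 <- kp_sensitivity("rat", reg, t_end = 14, tissues = "liver",
                          delta = 0, dt_out = 0.5)
  expect_equal(max(abs(sens0$pct_change_plasma_auc)), 0, tolerance = 1e-8)
  expect_equal(max(abs(sens0$pct_change_tissue_auc)), 0, tolerance = 1e-8)
  # a perturbed system still closes its mass balance
  p2 <- default_adc_parameters("rat")
  p2$payload$kp_table$Kp[p2$payload$kp_table$tissue == "liver"] <-
    p2$payload$kp_table$Kp[p2$payload$kp_table$tissue == "liver"] * 1.2
  aud <- mass_balance_audit(simulate_adc("rat", reg, t_end = 14, params = p2,
                                         dt_out = 0.5))
  expect_true(aud$ok)
})

test_that("ledger-based source attribution is normalized and process-consistent", {
  sim <- simulate_adc("rat", build_regimen("single", 5), t_end = 21,
                      dt_out = 0.5)
  att <- payload_source_attribution(sim)
  expect_false(att$all_zero)
  sums <- tapply(att$by_source$fraction, att$by_source$time_days, sum)
  expect_true(all(abs(sums[-1] - 1) < 1e-9))
  # without degradation every released molecule comes from deconjugation
  simd <- simulate_adc("rat", build_regimen("single", 5), t_end = 21,
                       params = params_with("rat", "mab.kdeg_base" = 0),
                       dt_out = 0.5)
  attd <- payload_source_attribution(simd)$by_process
  last <- attd[attd$time_days == 21, ]
  expect_equal(last$fraction[last$source == "deconjugation"], 1)
  expect_equal(last$fraction[last$source == "degradation"], 0)
  # zero dose: no release anywhere, flagged
  sim0 <- simulate_adc("rat", build_regimen("single", 0), t_end = 7,
                       dt_out = 1)
  expect_true(payload_source_attribution(sim0)$all_zero)
})
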