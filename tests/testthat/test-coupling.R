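dec1 <- default_adc_parameters("mouse")$deconjugation  # SF = 1

test_that("deconjugation rate has the published asymptotes and a frozen mid-range value", {
  expect_equal(kdec_of_dar(1e6, dec1), 0.0806, tolerance = 1e-10)
  expect_equal(kdec_of_dar(0, dec1), 0.0102)
  expect_equal(kdec_of_dar(1e-9, dec1), 0.0102, tolerance = 1e-6)
  # frozen high-precision evaluation of the empirical equation at DAR = 4
  expect_equal(kdec_of_dar(4, dec1), 0.080505150012, tolerance = 1e-10)
  # scaling factor multiplies the whole rate
  dec06 <- modifyList(dec1, list(SF = 0.6))
  expect_equal(kdec_of_dar(4, dec06), 0.6 * kdec_of_dar(4, dec1))
  expect_error(kdec_of_dar(-1, dec1), "DAR")
})

test_that("deconjugation rate is non-decreasing in DAR and bounded", {
  dar <- c(0, 10^seq(-6, 6, length.out = 200))
  k <- kdec_of_dar(dar, dec1)
  expect_true(all(diff(k) >= -1e-15))
  expect_true(all(k >= dec1$beta - 1e-15 & k <= dec1$alpha + 1e-15))
})

test_that("constant-rate DAR decline matches the exponential closed form", {
  p <- modifyList(dec1, list(beta = dec1$alpha, SF = 0.6))
  tt <- seq(0, 42, by = 0.5)
  dar <- simulate_dar(4, p, tt)
  expect_rel_equal(dar, 4 * exp(-dec1$alpha * 0.6 * tt), 1e-8)
  expect_equal(dar_derivative(0, dec1), 0)
})

test_that("default parameters give a biphasic DAR decline", {
  tt <- seq(0, 120, by = 0.5)
  dar <- simulate_dar(4, dec1, tt)
  expect_true(all(diff(dar) < 0))       # strictly decreasing
  expect_true(all(dar > 0 & dar <= 4))  # bounded by DAR0
  # initial log-slope ~ alpha (DAR^-tau negligible at DAR0 = 4),
  # late log-slope ~ beta (DAR well below 1)
  sl <- -diff(log(dar)) / diff(tt)
  expect_equal(sl[1], dec1$alpha, tolerance = 0.01)
  expect_equal(sl[length(sl)], dec1$beta, tolerance = 0.15)
  expect_gt(sl[1] / sl[length(sl)], 4)
})

test_that("allometric scaling reproduces the species factors and is monotone", {
  expect_equal(allometric_sf(0.028), 1.0)
  expect_equal(allometric_sf(c(0.28, 6.2, 70)), c(0.6, 0.3, 0.1))
  raw <- allometric_sf(c(0.28, 6.2, 70), digits = NULL)
  expect_false(any(raw == c(0.6, 0.3, 0.1)))  # rounding is a reporting step
  bw <- sort(stats::runif(20, 0.02, 100))
  expect_true(all(diff(allometric_sf(bw, digits = NULL)) < 0))
  expect_error(allometric_sf(-1), "weights")
})

test_that("species degradation rate is the mouse rate times the fold-change", {
  expect_equal(kdeg_for_species(30, 1), 30)
  expect_equal(kdeg_for_species(30, 3), 90)
  expect_equal(default_adc_parameters("monkey")$coupling$f_Kdeg, 3)
  expect_equal(default_adc_parameters("human")$coupling$f_Kdeg, 4)
})

test_that("hepatic clearance conversion follows CLint * BW * 0.06 * fup", {
  expect_equal(hepatic_clearance_rate(2.35, 0.767, 70),
               2.35 * 70 * 0.06 * 0.767)
  expect_equal(hepatic_clearance_rate(50, 0, 0.25), 0)
})

test_that("analyte assembly converts to reported units and round-trips through the DAR ratio", {
  a <- analyte_assembly(100, 4, 50, MW_mAb = 150000, MW_MMAE = 717.98)
  expect_equal(a$total_mab_ugml, 15)
  expect_equal(a$conjugated_mmae_ngml, 4 * 100 * 717.98 * 1e-3)
  expect_equal(a$unconjugated_mmae_ngml, 50 * 717.98 * 1e-3)
  expect_equal(analyte_assembly(100, 0, 50)$conjugated_mmae_ngml, 0)
  # inverse: the observed-DAR computation recovers the assembled DAR
  dar_in <- c(4, 2.5, 1, 0.2)
  tt <- 1:4
  asm <- analyte_assembly(c(100, 60, 30, 10), dar_in, 0)
  prof <- observed_dar_profile(
    data.frame(time_day = tt, conc = asm$conjugated_mmae_ngml),
    data.frame(time_day = tt, conc = asm$total_mab_ugml))
  expect_equal(prof$dar, dar_in, tolerance = 1e-12)
})

test_that("deconjugation release fluxes obey the bookkeeping identity", {
  tis <- data.frame(vascular = c(1, 2), endosomal_unbound = c(0.1, 0),
                    endosomal_bound = c(0.2, 0.1), interstitial = c(0.5, 1))
  st <- list(tissue = tis, blood = 3, lymph_node = 0.2)
  fl <- deconjugation_release_fluxes(st, DAR = 2, p = dec1)
  kd <- kdec_of_dar(2, dec1)
  expect_equal(fl$total, kd * 2 * (sum(tis) + 3 + 0.2))
  expect_equal(fl$tissue, kd * 2 * rowSums(tis))
  expect_equal(deconjugation_release_fluxes(st, 0, dec1)$total, 0)
  p0 <- modifyList(dec1, list(alpha = 0, beta = 0))
  expect_equal(deconjugation_release_fluxes(st, 2, p0)$total, 0)
})

test_that("degradation release is kdeg * amount * DAR", {
  expect_equal(degradation_release_flux(5, 30, 4), 600)
  expect_equal(degradation_release_flux(5, 0, 4), 0)
  expect_equal(degradation_release_flux(5, 30, 0), 0)
})
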