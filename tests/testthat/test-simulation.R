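test_that("regimens follow the published schedules", {
  expect_equal(build_regimen("single", 2.4)$times_days, 0)
  expect_equal(build_regimen("Q3W", 2.4, 2)$times_days, c(0, 21))
  expect_equal(build_regimen("Q3W", 2.4, 3)$times_days, c(0, 21, 42))
  expect_equal(build_regimen("weekly3_of_28", 1.0, 2)$times_days,
               c(0, 7, 14, 28, 35, 42))
  expect_error(build_regimen("biweekly", 1), "unknown regimen")
  expect_error(build_regimen("single", -1), "dose")
  expect_error(build_regimen("single", 1, 0), "n_cycles")
})

test_that("t_end before the last dose is rejected", {
  expect_error(simulate_adc("rat", build_regimen("Q3W", 1, 3), t_end = 30),
               "precedes the last dose")
})

test_that("a zero dose produces identically zero analyte trajectories", {
  sim <- simulate_adc("rat", build_regimen("single", 0), t_end = 7,
                      dt_out = 1)
  expect_true(all(sim$plasma$total_mab_nM == 0))
  expect_true(all(sim$plasma$unconjugated_mmae_nM == 0))
  expect_true(all(sim$plasma$dar == 0))
})

test_that("the simulated DAR matches the reference DAR ODE integration", {
  sim <- simulate_adc("rat", build_regimen("single", 10), t_end = 42)
  ref <- simulate_dar(4, default_adc_parameters("rat")$deconjugation,
                      sim$times)
  expect_rel_equal(sim$plasma$dar, ref, 1e-6)
  # DAR stays positive, non-increasing, bounded by DAR0
  expect_true(all(sim$plasma$dar > 0))
  expect_true(all(diff(sim$plasma$dar) <= 1e-12))
  expect_true(all(sim$plasma$dar <= 4 + 1e-12))
})

test_that("trajectories are dose-linear in the low-occupancy regime", {
  s1 <- simulate_adc("human", build_regimen("single", 1e-4), t_end = 21,
                     dt_out = 0.5)
  s2 <- simulate_adc("human", build_regimen("single", 2e-4), t_end = 21,
                     dt_out = 0.5)
  for (col in c("total_mab_nM", "unconjugated_mmae_nM")) {
    a <- 2 * s1$plasma[[col]]; b <- s2$plasma[[col]]
    expect_lt(max(abs(a - b) / pmax(b, max(b) * 1e-12)), 1e-6)
  }
})

test_that("tightening solver tolerances leaves plasma AUCs unchanged to 0.1%", {
  reg <- build_regimen("single", 5)
  s1 <- simulate_adc("rat", reg, t_end = 21, dt_out = 1)
  s2 <- simulate_adc("rat", reg, t_end = 21, dt_out = 1,
                     rtol = 1e-9, atol = 1e-13)
  for (col in c("total_mab_nM", "unconjugated_mmae_nM", "conjugated_mmae_nM")) {
    a1 <- auc_trapezoid(s1$times, s1$plasma[[col]])
    a2 <- auc_trapezoid(s2$times, s2$plasma[[col]])
    expect_lt(abs(a1 - a2) / a2, 1e-3)
  }
})

test_that("the mass-balance audit closes for default runs and flags corruption", {
  sim <- simulate_adc("rat", build_regimen("Q3W", 5, 2), t_end = 42,
                      dt_out = 0.5)
  aud <- mass_balance_audit(sim)
  expect_lt(aud$mab_rel_error, 1e-6)
  expect_lt(aud$payload_rel_error, 1e-6)
  expect_true(aud$ok)
  # ledgers are non-decreasing
  ix <- sim$ctx$ix
  for (cols in list(ix$ldec, ix$ldeg, ix$ldecp, ix$pel, ix$mdeg)) {
    expect_true(all(apply(sim$states[, cols, drop = FALSE], 2,
                          function(v) all(diff(v) >= -1e-9))))
  }
  corrupted <- sim
  corrupted$states[nrow(corrupted$states), ix$pel] <-
    corrupted$states[nrow(corrupted$states), ix$pel] + 0.1 * sim$dosed_nmol
  expect_false(mass_balance_audit(corrupted)$ok)
})

test_that("result export and tissue concentration tables are well-formed", {
  sim <- simulate_adc("rat", build_regimen("single", 10), t_end = 7,
                      dt_out = 1)
  tc <- tissue_concentrations(sim, tissues = c("liver", "kidney"))
  expect_setequal(unique(tc$tissue), c("liver", "kidney"))
  expect_true(all(tc$conc >= 0))
  path <- withr::local_tempfile(fileext = ".csv")
  write_result(sim, path)
  lines <- readLines(path)
  expect_true(any(grepl("params_md5", lines)))
  tab <- read.csv(path, comment.char = "#")
  expect_setequal(names(tab), c("time_days", "tissue", "subcompartment",
                                "analyte", "conc", "unit"))
})
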