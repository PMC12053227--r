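# derivative-level and conservation properties of the coupled system

test_that("the drug-free state has zero derivatives and negative states are rejected", {
  phys <- load_species_physiology("rat")
  p <- default_adc_parameters("rat")
  ctx <- build_context(phys, p)
  y0 <- initial_state(ctx)
  expect_true(all(adc_rhs(0, y0, ctx)[[1]] == 0))
  y0[1] <- -1
  expect_error(adc_rhs(0, y0, ctx), "negative state")
})

test_that("FcRn is conserved and antibody moles are conserved without degradation", {
  p <- params_with("rat", "mab.kdeg_base" = 0)
  sim <- simulate_adc("rat", build_regimen("single", 5), t_end = 42,
                      params = p)
  ix <- sim$ctx$ix
  # receptor conservation per tissue at every stored step
  tot <- sim$states[, ix$meb, drop = FALSE] +
    sim$states[, ix$fcr, drop = FALSE]
  ref <- matrix(sim$ctx$fcrn_amount, nrow(tot), ncol(tot), byrow = TRUE)
  expect_lt(max(abs(tot - ref) / ref), 1e-6)
  # mass conservation over >= 42 simulated days
  body <- rowSums(sim$states[, c(ix$mv, ix$meu, ix$meb, ix$mi)]) +
    sim$states[, ix$mb] + sim$states[, ix$mln]
  expect_lt(max(abs(body - sim$dosed_nmol)) / sim$dosed_nmol, 1e-7)
  expect_equal(max(sim$states[, ix$mdeg]), 0)
})

test_that("FcRn is conserved under default degradation too", {
  sim <- simulate_adc("human", build_regimen("single", 2.4), t_end = 21,
                      dt_out = 0.5)
  ix <- sim$ctx$ix
  tot <- sim$states[, ix$meb, drop = FALSE] +
    sim$states[, ix$fcr, drop = FALSE]
  ref <- matrix(sim$ctx$fcrn_amount, nrow(tot), ncol(tot), byrow = TRUE)
  expect_lt(max(abs(tot - ref) / ref), 1e-6)
})

test_that("increasing the degradation rate strictly decreases total-antibody AUC", {
  aucs <- vapply(c(10, 30, 90), function(k) {
    sim <- simulate_adc("rat", build_regimen("single", 5), t_end = 21,
                        params = params_with("rat", "mab.kdeg_base" = k),
                        dt_out = 0.5)
    auc_trapezoid(sim$times, sim$plasma$total_mab_nM)
  }, numeric(1))
  expect_true(all(diff(aucs) < 0))
})

test_that("without pinocytosis and lymph flow the plasma pool is a closed, flat system", {
  p <- params_with("rat", "mab.CL_up" = 0, "mab.kdeg_base" = 0)
  phys <- phys_with("rat", L_lymph = 0)
  phys$tissues$Q_plasma[phys$tissues$name == "lymph_node"] <- 0
  sim <- simulate_adc("rat", build_regimen("single", 5), t_end = 21,
                      params = p, phys = phys, dt_out = 0.25)
  ix <- sim$ctx$ix
  vasc <- rowSums(sim$states[, ix$mv]) + sim$states[, ix$mb]
  expect_lt(max(abs(vasc - sim$dosed_nmol)) / sim$dosed_nmol, 1e-8)
  # after vascular mixing the plasma concentration is flat (analytic
  # no-elimination limit: amount / total vascular volume)
  late <- sim$plasma$total_mab_nM[sim$times >= 2]
  c_inf <- sim$dosed_nmol / (sum(sim$ctx$Vp) + sim$ctx$Vbp)
  expect_lt(max(abs(late - c_inf)) / c_inf, 1e-6)
})

test_that("interstitial:vascular ratio approaches (1-sigma_v)/(1-sigma_i) in a closed system", {
  # elevated lymph flow shortens the interstitial equilibration time; the
  # asymptotic ratio is set by the reflection coefficients alone
  p <- params_with("rat", "mab.CL_up" = 0, "mab.kdeg_base" = 0)
  run <- function(phys) {
    sim <- simulate_adc("rat", build_regimen("single", 5), t_end = 120,
                        params = p, phys = phys, dt_out = 2)
    mab_steady_ratio_check(sim)
  }
  phys <- phys_with("rat", sigma_i = 0)
  per <- phys$tissues$name %in% adc_tissues
  phys$tissues$L_lymph[per] <- 0.02 * phys$tissues$Q_plasma[per]
  chk <- run(phys)
  expect_true(all(chk$steady))
  expect_equal(chk$ratio, 1 - phys$tissues$sigma_v[per], tolerance = 1e-3)

  # sigma_v = 1: nothing crosses the vascular wall, ratio 0
  phys2 <- phys; phys2$tissues$sigma_v[per] <- 1
  chk2 <- run(phys2)
  expect_equal(chk2$ratio, rep(0, sum(per)), tolerance = 1e-12)

  # sigma_v = 0, sigma_i = 0: free filtration, ratio 1
  phys3 <- phys; phys3$tissues$sigma_v[per] <- 0
  chk3 <- run(phys3)
  expect_equal(chk3$ratio, rep(1, sum(per)), tolerance = 1e-3)
})

test_that("payload moles are conserved without hepatic clearance or sources", {
  p <- params_with("rat", "payload.CLint" = 0)
  sim <- simulate_adc("rat", build_regimen("single", 0), t_end = 21,
                      params = p, init_payload_nmol = 10, dt_out = 0.5)
  ix <- sim$ctx$ix
  tot <- rowSums(sim$states[, c(ix$pec, ix$pbc, ix$pcl)]) +
    sim$states[, ix$ppb] + sim$states[, ix$pbb]
  expect_lt(max(abs(tot - 10)) / 10, 1e-8)
  aud <- mass_balance_audit(sim)
  expect_lt(aud$payload_rel_error, 1e-6)
})

test_that("cellular exchange vanishes at the Kp equilibrium in every tissue", {
  phys <- load_species_physiology("human")
  p <- default_adc_parameters("human")
  ctx <- build_context(phys, p)
  y <- initial_state(ctx)
  cec <- 5  # nM
  y[ctx$ix$pec] <- cec * ctx$Vec
  y[ctx$ix$pcl] <- cec * ctx$Kp * ctx$Vc
  y[ctx$ix$pbc] <- cec * ctx$KpBC * ctx$Vbc
  y[ctx$ix$ppb] <- cec * ctx$Vbp
  y[ctx$ix$pbb] <- cec * ctx$KpBC * ctx$Vbcb
  dy <- adc_rhs(0, y, ctx)[[1]]
  # cellular and blood-cell pools see zero net flux in every tissue
  expect_lt(max(abs(dy[c(ctx$ix$pcl, ctx$ix$pbc, ctx$ix$pbb)])), 1e-10)
  # with all extracellular concentrations equal, perfusion exchange nets to
  # zero and only hepatic elimination remains (in liver)
  ih <- ctx$i_liver
  # residual bounded by the file precision of the flow table, relative to
  # the perfusion flux scale
  expect_lt(max(abs(dy[ctx$ix$pec][-ih])) / (max(ctx$Q) * cec), 1e-8)
  expect_equal(dy[ctx$ix$pec][ih], -ctx$CLhep * cec, tolerance = 1e-8)
})

test_that("unconjugated-payload AUC strictly decreases as CLint increases", {
  aucs <- vapply(c(2.35, 10, 40), function(cl) {
    sim <- simulate_adc("human", build_regimen("single", 0), t_end = 14,
                        params = params_with("human", "payload.CLint" = cl),
                        init_payload_nmol = 100, dt_out = 0.5)
    auc_trapezoid(sim$times, sim$plasma$unconjugated_mmae_nM)
  }, numeric(1))
  expect_true(all(diff(aucs) < 0))
})
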