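test_that("simulation is reproducible given a seed", {
  spec <- simulation_spec(preset_conditions()$series1_syngas)
  set.seed(99); a <- simulate_batch(spec)
  set.seed(99); b <- simulate_batch(spec)
  expect_identical(a$liquid_final, b$liquid_final)
  expect_identical(a$gas_final, b$gas_final)
  r1 <- run_enrichment(spec, seed = 5)
  r2 <- run_enrichment(spec, seed = 5)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$observations[[7]]$liquid_final,
                   r2$observations[[7]]$liquid_final)
})

test_that("noiseless vials conserve mass and electrons", {
  spec <- simulation_spec(preset_conditions()$series1_syngas, noise_cv = 0)
  set.seed(7)
  for (i in 1:50) {
    obs <- simulate_batch(spec)
    expect_equal(emol_recovery(obs, REG), 100, tolerance = 1e-9)
    y <- batch_ledger(obs, REG)$yields_percent
    expect_equal(sum(y[y > 0]), 100, tolerance = 1e-9)
  }
})

test_that("a single-reaction noiseless spec reproduces the exact batch", {
  spec <- simulation_spec(inert_condition(),
                          extent_mean = c(R6 = 1),
                          extent_dispersion = 0, noise_cv = 0)
  set.seed(1)
  obs <- simulate_batch(spec)
  lg <- batch_ledger(obs, REG)
  expect_equal(lg$yields_percent[["butyric acid"]], 95.24, tolerance = 0.005)
  expect_equal(lg$yields_percent[["H2"]], 4.76, tolerance = 0.005)
  expect_equal(lg$recovery_percent, 100, tolerance = 1e-9)
})

test_that("infeasible draws are truncated, never negative", {
  spec <- simulation_spec(inert_condition(c("ethanol" = 50,
                                            "acetic acid" = 30)),
                          extent_mean = c(R6 = 50),  # far beyond substrate
                          extent_dispersion = 0, noise_cv = 0)
  set.seed(2)
  obs <- simulate_batch(spec)
  expect_true(all(obs$liquid_final >= 0))
  # all ethanol consumed, extent capped at 1 by the 5 mmol of ethanol
  expect_equal(attr(obs, "truth")[["R6"]], 1, tolerance = 1e-9)
  expect_error(simulate_batch(simulation_spec(
    inert_condition(setNames(numeric(0), character(0))))),
    "no substrate")
})

test_that("carry-over adds the inoculum fraction to fresh medium", {
  spec <- simulation_spec(preset_conditions()$series1_syngas,
                          noise_cv = 0, carryover = 0.18)
  inoc <- c("butyric acid" = 20, "ethanol" = 10)
  set.seed(3)
  obs <- simulate_batch(spec, inoculum_mM = inoc)
  expect_equal(obs$liquid_initial[["butyric acid"]], 0.18 * 20,
               tolerance = 1e-9)
  expect_equal(obs$liquid_initial[["ethanol"]], 93 + 0.18 * 10,
               tolerance = 1e-9)
})

test_that("selection trace degenerates to identity with one replicate", {
  spec <- simulation_spec(preset_conditions()$series1_syngas,
                          replicates = 1, transfers = 3)
  run <- run_enrichment(spec, seed = 8)
  expect_equal(run$trace$selected, sprintf("t%d_v1", 0:2))
  expect_length(run$observations, 3)
})

test_that("no selection signal without gain or noise", {
  spec <- simulation_spec(preset_conditions()$series1_syngas,
                          extent_dispersion = 0, noise_cv = 0, gain = 1)
  run <- run_enrichment(spec, seed = 4)
  expect_equal(diff(range(run$trace$target_yield)), 0, tolerance = 1e-9)
})

test_that("enrichment gain raises the expected target yield", {
  spec <- simulation_spec(preset_conditions()$series1_syngas)
  ty <- vapply(1:25, function(s) run_enrichment(spec, seed = s)$trace$target_yield,
               numeric(spec$transfers))
  means <- rowMeans(ty)
  expect_true(all(diff(means) >= 0))
})

test_that("recovery study reports per-reaction errors and recovery spread", {
  spec <- simulation_spec(preset_conditions()$series1_syngas)
  rs <- recovery_study(spec, n_runs = 30, seed = 12)
  expect_true(rs$full_rank)
  expect_setequal(rs$summary$reaction, names(spec$extent_mean))
  expect_true(all(rs$summary$median_rel_error < 0.10))
  expect_lt(median(abs(rs$recovery - 100)), 3)
  # zero noise, zero dispersion: exact recovery of the means
  spec0 <- simulation_spec(preset_conditions()$series1_syngas,
                           extent_dispersion = 0, noise_cv = 0)
  rs0 <- recovery_study(spec0, n_runs = 2, seed = 1)
  expect_equal(max(rs0$per_run$rel_error), 0, tolerance = 1e-7)
  expect_equal(rs0$recovery, c(100, 100), tolerance = 1e-9)
})
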