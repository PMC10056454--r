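test_that("every default reaction conserves C, H, O and electrons", {
  for (net in list(default_network(REG), default_network(REG, caproate_rbo = TRUE))) {
    for (r in net$reactions) {
      chk <- check_balance(r, REG)
      expect_true(chk$balanced, info = r$name)
      expect_equal(unname(chk$element_residuals), rep(0, 4), info = r$name)
      expect_equal(chk$electron_residual, 0, info = r$name)
      sides <- electron_sides(r, REG)
      expect_equal(sides[["substrates"]], sides[["products"]],
                   info = r$name)
    }
  }
})

test_that("the elongation reaction carries 84 electrons per side", {
  r6 <- default_network(REG)$reactions$R6
  expect_equal(unname(electron_sides(r6, REG)), c(84, 84))
  # 0.4 H2 released per mol ethanol in butyrate elongation, none in caproate
  expect_equal(r6$coefficients[["H2"]] / -r6$coefficients[["ethanol"]], 0.4)
  r7 <- default_network(REG)$reactions$R7
  expect_false("H2" %in% names(r7$coefficients))
})

test_that("perturbed stoichiometry is rejected with residuals reported", {
  broken <- reaction("bad", c("ethanol" = -5, "acetic acid" = -3,
                              "butyric acid" = 3, "H2" = 2, "H2O" = 3))
  chk <- check_balance(broken, REG)
  expect_false(chk$balanced)
  expect_equal(chk$element_residuals[["C"]], -4)
  expect_equal(chk$electron_residual, -20)
  expect_error(reaction_network(list(broken), REG), "not balanced")
  # textbook homoacetogenesis balances: 2 CO2 + 4 H2 -> acetate + 2 H2O
  homo <- reaction("homo", c("CO2" = -2, "H2" = -4, "acetic acid" = 1,
                             "H2O" = 2))
  expect_true(check_balance(homo, REG)$balanced)
  expect_equal(unname(electron_sides(homo, REG)), c(8, 8))
})

test_that("apply_extents advances the state and respects feasibility", {
  net <- default_network(REG)
  x0 <- c("ethanol" = 5, "acetic acid" = 3)
  # zero extent: nothing happens
  same <- apply_extents(net, c(R6 = 0), x0)
  expect_equal(same[["ethanol"]], 5)
  fin <- apply_extents(net, c(R6 = 1), x0)
  expect_equal(fin[["ethanol"]], 0)
  expect_equal(fin[["acetic acid"]], 0)
  expect_equal(fin[["butyric acid"]], 4)
  expect_equal(fin[["H2"]], 2)
  expect_error(apply_extents(net, c(R6 = 1.2), x0), "infeasible.*ethanol")
  expect_error(apply_extents(net, c(R6 = 1), c("unicornol" = 1)),
               "outside the network")
})

test_that("extent estimation recovers noiseless extents and round-trips", {
  net <- default_network(REG)
  active <- c("R1", "R2", "R6", "R7", "R8")
  xi_true <- c(R1 = 0.9, R2 = 0.25, R6 = 0.4, R7 = 0.2, R8 = 0.07)
  x0 <- c("ethanol" = 9.3, "acetic acid" = 3.9, "H2" = 9.9, "CO" = 1.4,
          "CO2" = 2.8, "H2O" = 100)
  fin <- apply_extents(net, xi_true, x0)
  x0_full <- setNames(numeric(nrow(net$S)), rownames(net$S))
  x0_full[names(x0)] <- x0
  delta <- (fin - x0_full)[net$measured]
  fit <- estimate_extents(net, delta, reactions = active)
  expect_true(fit$full_rank)
  expect_equal(unname(fit$extents[active]), unname(xi_true[active]),
               tolerance = 1e-8)
  expect_lt(fit$residual_norm, 1e-8)
  # zero change -> zero extents
  fit0 <- estimate_extents(net, setNames(numeric(0), character(0)),
                           reactions = active)
  expect_equal(unname(fit0$extents), rep(0, 5))
})

test_that("rank deficiency (a reaction and its reverse) is reported", {
  net <- default_network(REG)
  expect_warning(
    fit <- estimate_extents(net, c("ethanol" = 1, "acetic acid" = -1),
                            reactions = c("R5", "R9")),
    "rank-deficient")
  expect_false(fit$full_rank)
})

test_that("network YAML round-trips with balance checking on read", {
  net <- default_network(REG)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_network(net, path)
  net2 <- read_network(path, REG)
  expect_identical(colnames(net2$S), colnames(net$S))
  expect_equal(net2$S[rownames(net$S), ], net$S)
})
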