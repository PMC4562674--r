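test_that("an empty free set is a no-op", {
  p <- params_raw()
  p2 <- calibrate_parameters(homeostasis_anchors(), p, free = character())
  expect_identical(unlist(p2), unlist(p))
})

test_that("calibrated parameters reproduce their closed-form balances", {
  anch <- homeostasis_anchors()
  p <- calibrate_parameters(anch, params_raw())
  ss <- solve_homeostasis(p)
  st <- ss$state
  ## independent hand rearrangement of the fibroblast balance:
  ## lambda_Ef E0* = d_f f* + (f->m transition at anchor cytokines) f*
  hTb <- anch$Tb / (p$K_Tbeta + anch$Tb)
  hG <- st[["G"]] / (p$K_G + st[["G"]])
  lhs <- p$lambda_Ef * anch$E0
  rhs <- p$d_f * anch$f + (p$lambda_mfT * hTb + p$lambda_mfG * hG) * anch$f
  expect_equal(lhs, rhs, tolerance = 1e-10)
  ## TNF-alpha balance with the total-epithelium source
  hTa <- anch$Ta / (p$K_Talpha + anch$Ta)
  expect_equal(p$lambda_TalphaE * anch$E0 + p$lambda_TalphaM * st[["M1"]],
               p$d_Talpha * anch$Ta + p$lambda_MTalpha * hTa * st[["M2"]],
               tolerance = 1e-10)
  ## provenance tagging
  info <- as.data.frame(p)
  expect_true(all(info$provenance[info$name %in%
    c("lambda_M1", "lambda_TalphaE", "A_E0", "lambda_Ef", "d_rho")] ==
      "calibrated"))
})

test_that("the calibrated steady state hits the printed anchors", {
  anch <- homeostasis_anchors()
  ss <- solve_homeostasis(default_parameters(calibrated = TRUE))
  expect_true(ss$converged)
  expect_lt(ss$residual, 1e-12)
  expect_equal(ss$state[["E0"]], anch$E0, tolerance = 1e-8)
  expect_equal(ss$state[["f"]], anch$f, tolerance = 1e-8)
  expect_equal(ss$state[["rho"]], anch$rho, tolerance = 1e-8)
  expect_equal(ss$state[["Ta"]], anch$Ta, tolerance = 1e-8)
  expect_equal(ss$state[["Tb"]], anch$Tb, tolerance = 1e-8)
  expect_identical(ss$state[["E"]], 0)
  ## IL-13 rest level is close to its source/decay ratio
  expect_equal(ss$state[["I13"]], 2.12e-7 / 12.47, tolerance = 2e-3)
})

test_that("unsupported or degenerate free parameters are rejected", {
  expect_error(calibrate_parameters(free = "lambda_fE"), "lambda_fE")
  expect_error(calibrate_parameters(free = "lambda_QM"), "lambda_QM")
  ## an implausibly small TNF-alpha anchor drives the epithelial source
  ## negative
  anch <- homeostasis_anchors()
  anch$Ta <- 1e-13
  expect_error(calibrate_parameters(anch, params_raw()), "lambda_TalphaE")
})

test_that("the fixed point persists under forward integration", {
  p <- default_parameters(calibrated = TRUE)
  ss <- solve_homeostasis(p)
  v30 <- verify_fixed_point(ss, p, horizon = 30)
  expect_lt(v30$max_drift, 1e-3)
  v300 <- verify_fixed_point(ss, p, horizon = 300)
  expect_lt(v300$max_drift, 1e-3)
})

test_that("the root is recovered from perturbed starting guesses", {
  p <- default_parameters(calibrated = TRUE)
  ref <- solve_homeostasis(p)$state
  set.seed(123)
  for (i in 1:10) {
    start <- ref * exp(runif(14, log(0.5), log(1.5)))
    start["E"] <- 0
    ss <- solve_homeostasis(p, start = start)
    expect_true(ss$converged)
    expect_equal(ss$state, ref, tolerance = 1e-6)
  }
})
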