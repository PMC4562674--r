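test_that("tissue volume fraction follows the cubic-hole formula", {
  expect_equal(volume_fraction(1 / 7), 127 / 343, tolerance = 1e-15)
  expect_identical(volume_fraction(1), 1)
  expect_equal(volume_fraction(1 / 2), 7 / 8)
  expect_error(volume_fraction(0), "theta")
  expect_error(volume_fraction(1.2), "theta")
})

test_that("an unperforated cell yields the identity tensor", {
  et <- solve_cell_problem(unit_cell(theta = 1, resolution = 8))
  expect_equal(et$a, diag(3))
  expect_equal(et$gamma, 1)
})

test_that("the effective tensor has cubic symmetry", {
  et <- solve_cell_problem(unit_cell(1 / 7, 14))
  a <- et$a
  expect_equal(a, t(a))
  expect_lt(abs(a[1, 1] - a[2, 2]), 1e-6)
  expect_lt(abs(a[2, 2] - a[3, 3]), 1e-6)
  expect_lt(max(abs(a[upper.tri(a)])), 1e-8)
  expect_true(a[1, 1] > 0 && a[1, 1] <= 1)
  ## zero-mean corrector gauge
  expect_lt(max(abs(et$chi_mean)), 1e-10)
  expect_lt(et$residual, 1e-10)
})

test_that("a larger hole obstructs diffusion more", {
  ## theta = 3/7 (hole edge 4/7) vs theta = 1/7 (hole edge 6/7), both
  ## voxel-exact at resolution 14
  a_big_hole <- solve_cell_problem(unit_cell(1 / 7, 14))$a[1, 1]
  a_small_hole <- solve_cell_problem(unit_cell(3 / 7, 14))$a[1, 1]
  expect_lt(a_big_hole, a_small_hole)
})

test_that("diagonal entries form a Cauchy sequence under refinement", {
  vals <- vapply(c(14, 28, 42),
                 function(n) solve_cell_problem(unit_cell(1 / 7, n))$a[1, 1],
                 numeric(1))
  expect_lt(abs(vals[3] - vals[2]), abs(vals[2] - vals[1]))
})

test_that("the converged diagonal respects the tissue-channel lower bound", {
  ## a divergence-free unit current through the straight tissue channels
  ## gives sigma_eff >= 1 - (1-theta)^2; the tissue fraction is an upper
  ## bound
  a <- solve_cell_problem(unit_cell(1 / 7, 28))$a[1, 1]
  expect_gt(a, 1 - (6 / 7)^2 - 1e-6)
  expect_lt(a, volume_fraction(1 / 7))
})

test_that("effective diffusion rescales by a11 / gamma", {
  expect_identical(effective_diffusion(0, reference_tensor()), 0)
  ## published tensor: 0.11 * (343/127) * D
  expect_equal(effective_diffusion(8.64e-7, reference_tensor()),
               2.57e-7, tolerance = 2e-3)
  ident <- list(a = diag(3), gamma = 1)
  expect_equal(effective_diffusion(4.32e-2, ident), 4.32e-2)
  expect_error(effective_diffusion(1, list(a = diag(3), gamma = 0)), "gamma")
  expect_error(effective_diffusion(-1, reference_tensor()), "non-negative")
})
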