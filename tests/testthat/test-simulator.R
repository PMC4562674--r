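p_cal <- default_parameters(calibrated = TRUE)
base_ss <- solve_homeostasis(p_cal)

test_that("damage boxes rasterize to the expected indicators", {
  g <- sim_grid(20)
  ind <- rasterize_damage(damage_box(edge = 0.3), g)
  expect_equal(sum(ind), 216)           # 6 cells per axis
  expect_equal(average_concentration(ind, g), 0.027)
  expect_equal(sum(rasterize_damage(NULL, g)), 0)
  expect_equal(sum(rasterize_damage(damage_box(edge = 1), g)), 8000)
  expect_error(damage_box(center = c(0.9, 0.5, 0.5), edge = 0.3), "inside")
})

test_that("domain averages are exact cell means and linear", {
  g <- sim_grid(c(4, 5, 6))
  expect_equal(average_concentration(array(3.7, g$K), g), 3.7)
  set.seed(21)
  F1 <- array(runif(prod(g$K)), g$K); F2 <- array(runif(prod(g$K)), g$K)
  expect_equal(average_concentration(2 * F1 - 3 * F2, g),
               2 * average_concentration(F1, g) -
                 3 * average_concentration(F2, g))
})

test_that("the homogenized Laplacian matches a brute-force stencil and conserves mass", {
  g <- sim_grid(c(5, 4, 6))
  set.seed(22)
  u <- array(rnorm(prod(g$K)), g$K)
  expect_equal(homogenized_laplacian(u, g, 0.37),
               oracle_laplacian(u, g$K, 0.37), tolerance = 1e-12)
  expect_equal(homogenized_laplacian(array(2.2, g$K), g, 1),
               array(0, g$K))
  for (i in 1:50) {
    u <- array(rnorm(prod(g$K)), g$K)
    out <- homogenized_laplacian(u, g, 1)
    expect_lt(abs(sum(out)) / (prod(g$K) * max(abs(out))), 1e-12)
  }
})

test_that("axis cosine modes are eigenfunctions of the discrete operator", {
  K <- 12
  g <- sim_grid(K)
  x <- g$coords[[1]]
  u <- array(rep(cos(pi * x), K * K), c(K, K, K))
  lam <- -4 * K^2 * sin(pi / (2 * K))^2
  expect_equal(homogenized_laplacian(u, g, 1), lam * u, tolerance = 1e-9)
})

test_that("chemotaxis moves mass without creating it", {
  g <- sim_grid(5)
  set.seed(23)
  for (scheme in c("upwind", "central")) {
    M1 <- array(runif(125), g$K); P <- array(runif(125) * 1e-8, g$K)
    out <- chemotaxis_term(M1, P, g, 10, scheme = scheme)
    expect_equal(out, oracle_chemotaxis(M1, P, g$K, 10, scheme == "upwind"),
                 tolerance = 1e-12)
    expect_lt(abs(sum(out)) / max(abs(out)), 1e-10)
  }
  expect_equal(chemotaxis_term(array(runif(125), g$K),
                               array(4e-9, g$K), g, 10),
               array(0, g$K))
  expect_equal(chemotaxis_term(array(1, g$K), array(runif(125), g$K), g, 0),
               array(0, g$K))
})

test_that("a chemoattractant peak draws mass from its neighbours", {
  g <- sim_grid(5)
  M1 <- array(1e-5, g$K)
  P <- array(0, g$K); P[3, 3, 3] <- 1e-8
  out <- chemotaxis_term(M1, P, g, 10)
  expect_gt(out[3, 3, 3], 0)
  expect_lt(out[2, 3, 3], 0)
  expect_lt(out[3, 4, 3], 0)
  expect_lt(abs(sum(out)) / max(abs(out)), 1e-10)
})

test_that("uniform damage reduces the PDE to the homogeneous ODE system", {
  sc <- make_fixture("uniform-ode", duration = 2, method = "rk4")
  res <- simulate(sc, baseline = base_ss)
  x_ode <- oracle_ode_rk4(base_ss$state, sc$params, ID = 1, dt = res$dt,
                          n_steps = round(2 / res$dt),
                          inflammation = sc$inflammation)
  x_pde <- fold_change(res, day = 2)$value[species_names()]
  expect_equal(x_pde, x_ode, tolerance = 1e-8)
})

test_that("homeostasis persists in a no-damage simulation", {
  sc <- make_fixture("no-damage", grid = 4, duration = 30)
  res <- simulate(sc, baseline = base_ss)
  fc <- fold_change(res)
  drift <- abs(fc$ratio[setdiff(species_names(), "E")] - 1)
  expect_lt(max(drift), 1e-3)
  expect_equal(fc$value[["E"]], 0, tolerance = 1e-12)
  expect_equal(fc$value[["S"]], 0, tolerance = 1e-12)
})

test_that("the exponential and explicit schemes agree on a one-day run", {
  scr <- make_fixture("tiny-disease", duration = 1, method = "rk4")
  sce <- make_fixture("tiny-disease", duration = 1, dt = 0.002)
  v_r <- fold_change(simulate(scr, baseline = base_ss), day = 1)$value
  v_e <- fold_change(simulate(sce, baseline = base_ss), day = 1)$value
  rel <- abs(v_e - v_r) / pmax(abs(v_r), 1e-300)
  expect_lt(max(rel[setdiff(names(rel), c("E", "S"))]), 1e-4)
})

test_that("two-rate stepping reproduces the single-rate trajectory", {
  sc1 <- make_fixture("tiny-disease", grid = 4, duration = 60)
  sc2 <- make_fixture("tiny-disease", grid = 4, duration = 60, dt_slow = 0.1)
  v1 <- fold_change(simulate(sc1, baseline = base_ss))$value
  v2 <- fold_change(simulate(sc2, baseline = base_ss))$value
  rel <- abs(v2 - v1) / pmax(abs(v1), 1e-300)
  expect_lt(max(rel[setdiff(names(rel), "S")]), 1e-3)
})

test_that("short disease runs stay non-negative and record snapshots", {
  sc <- make_fixture("tiny-disease", snapshot_days = 2)
  res <- simulate(sc, baseline = base_ss)
  expect_true(all(res$averages >= 0))
  expect_named(res$snapshots, "day_2")
  expect_true(all(vapply(res$snapshots$day_2, function(a) all(a >= 0),
                         logical(1))))
  expect_true(all(diff(res$times) > 0))
})
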