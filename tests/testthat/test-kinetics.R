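test_that("hill saturation behaves and rejects bad input", {
  expect_identical(hill(0, 5e-9), 0)
  expect_equal(hill(5e-9, 5e-9), 0.5)
  expect_equal(hill(2e-7, 2e-7), 0.5)   # half-saturation at K_I13
  x <- seq(0, 1e-6, length.out = 50)
  h <- hill(x, 5e-9)
  expect_true(all(h >= 0 & h < 1))
  expect_true(all(diff(h) > 0))
  expect_error(hill(-1e-9, 5e-9), "negative")
  expect_error(hill(1e-9, 0), "positive")
  expect_error(hill(1e-9, -2), "positive")
})

test_that("only the constant sources survive at the all-zero state", {
  p <- params_raw()
  st <- setNames(rep(0, 14), species_names())
  r <- reaction_rates(st, p, damage = 0)
  expect_equal(r[["E0"]], p$A_E0)
  expect_equal(r[["I13"]], p$lambda_I13)
  expect_equal(unname(r[setdiff(names(r), c("E0", "I13"))]),
               rep(0, 12))
})

test_that("a lone M2 population drives PDGF production at lambda_GM * M2", {
  p <- params_raw()
  st <- setNames(rep(0, 14), species_names())
  st["M2"] <- 1e-6
  r <- reaction_rates(st, p)
  expect_equal(r[["G"]], 2.4e-11, tolerance = 1e-12)
  expect_equal(r[["G"]], p$lambda_GM * 1e-6)
})

test_that("rates agree with an independent literal transcription", {
  p <- params_raw()
  set.seed(42)
  for (i in 1:100) {
    st <- random_state()
    ID <- sample(c(0, 1), 1)
    r <- reaction_rates(st, p, damage = ID)
    ro <- oracle_rates(st, p, ID = ID)
    expect_equal(r, ro[names(r)], tolerance = 1e-12)
  }
})

test_that("macrophage phenotype switching conserves total macrophage flux", {
  set.seed(7)
  for (i in 1:20) {
    st <- random_state()
    p1 <- params_raw()
    p2 <- set_param(set_param(p1, "lambda_MT", runif(1, 0, 1)),
                    "lambda_M1", runif(1, 0, 1))
    s1 <- sum(reaction_rates(st, p1)[c("M1", "M2")])
    s2 <- sum(reaction_rates(st, p2)[c("M1", "M2")])
    expect_equal(s1, s2, tolerance = 1e-12)
  }
})

test_that("fibroblast-to-myofibroblast transition is equal and opposite", {
  set.seed(8)
  for (i in 1:20) {
    st <- random_state()
    p1 <- params_raw()
    p2 <- set_param(set_param(p1, "lambda_mfT", runif(1, 0, 1)),
                    "lambda_mfG", runif(1, 0, 1))
    s1 <- sum(reaction_rates(st, p1)[c("f", "m")])
    s2 <- sum(reaction_rates(st, p2)[c("f", "m")])
    expect_equal(s1, s2, tolerance = 1e-12)
  }
})

test_that("without damage the epithelium sees no activation or repair", {
  p <- params_raw()
  set.seed(9)
  for (i in 1:10) {
    st <- random_state()
    r <- reaction_rates(st, p, damage = 0)
    expect_equal(r[["E"]], -p$d_E * st[["E"]], tolerance = 1e-12)
    ## E0 must not depend on the damage-gated constants
    p2 <- set_param(set_param(p, "lambda_E0", 99), "lambda_1", 99)
    expect_equal(reaction_rates(st, p2, damage = 0)[["E0"]], r[["E0"]])
  }
})

test_that("production/loss split is consistent and non-negative", {
  p <- params_raw()
  set.seed(10)
  st <- random_state()
  pl <- reaction_rates(st, p, damage = 1, split = TRUE)
  expect_true(all(pl$production >= 0))
  expect_true(all(pl$loss >= 0))
  expect_equal(pl$production - pl$loss, reaction_rates(st, p, damage = 1))
})

test_that("rates reject invalid states and work on fields", {
  p <- params_raw()
  st <- random_state()
  st["f"] <- -1e-9
  expect_error(reaction_rates(st, p), "negative")
  st["f"] <- NaN
  expect_error(reaction_rates(st, p), "non-finite")
  ## elementwise evaluation over arrays matches pointwise calls
  set.seed(11)
  fld <- lapply(setNames(species_names(), species_names()),
                function(s) array(random_state()[[s]] *
                                    exp(runif(8, -0.1, 0.1)), c(2, 2, 2)))
  rf <- reaction_rates(fld, p, damage = array(c(0, 1), c(2, 2, 2)))
  one <- vapply(fld, function(a) a[2, 1, 1], numeric(1))
  r1 <- reaction_rates(one, p, damage = 1)
  expect_equal(vapply(rf, function(a) a[2, 1, 1], numeric(1)), r1,
               tolerance = 1e-14)
})

test_that("scar density is the clamped ECM excess", {
  p <- params_raw()
  expect_identical(scar_density(p$rho_star, p), 0)
  expect_identical(scar_density(p$rho_star / 2, p), 0)
  expect_equal(scar_density(p$rho_star + 1e-3, p), 1e-3)
  expect_error(scar_density(-1e-3, p), "negative")
})

test_that("species table marks transport roles correctly", {
  sp <- species_table()
  expect_equal(nrow(sp), 15)
  expect_equal(sum(sp$dynamic), 14)
  expect_false(any(sp$diffusing[sp$name %in% c("E0", "E")]))
  expect_identical(sp$name[sp$chemotactic], "M1")
})
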