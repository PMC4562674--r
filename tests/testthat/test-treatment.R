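test_that("the treatment ramp is 0 before, linear during, 1 after", {
  r <- drug_regimen("anti_TNFa", B1 = 1)
  expect_identical(ramp_fraction(99, r), 0)
  expect_identical(ramp_fraction(0, r), 0)
  expect_equal(ramp_fraction(110, r), 0.5)
  expect_identical(ramp_fraction(120, r), 1)
  expect_identical(ramp_fraction(300, r), 1)
  ## continuity at the window edges
  eps <- 1e-9
  expect_lt(abs(ramp_fraction(100 + eps, r) - ramp_fraction(100 - eps, r)),
            1e-6)
  expect_lt(abs(ramp_fraction(120 + eps, r) - ramp_fraction(120 - eps, r)),
            1e-6)
  r0 <- drug_regimen("anti_TNFa", start_day = 5, ramp_days = 0)
  expect_identical(ramp_fraction(4.9, r0), 0)
  expect_identical(ramp_fraction(5, r0), 1)
  expect_error(drug_regimen("anti_everything"), "unknown drug")
  expect_error(drug_regimen("anti_TNFa", B1 = -1), "non-negative")
})

test_that("zero amplitudes leave the kinetics untouched", {
  p <- params_raw()
  set.seed(31)
  st <- random_state()
  reg <- drug_regimen("anti_TGFb", A = 0, B = 0)
  mod <- drug_modifier(reg, t = 200)
  expect_identical(reaction_rates(st, p, drug = mod),
                   reaction_rates(st, p))
  ## before the start day any regimen is inert
  mod2 <- drug_modifier(drug_regimen("anti_TGFb", A = 2, B = 2), t = 50)
  expect_identical(reaction_rates(st, p, drug = mod2),
                   reaction_rates(st, p))
})

test_that("anti-TNF-alpha halves the M2 to M1 switching flux at B1 = 1", {
  p <- params_raw()
  set.seed(32)
  for (i in 1:10) {
    st <- random_state()
    mod <- drug_modifier(drug_regimen("anti_TNFa", B1 = 1), t = 200)
    r0 <- reaction_rates(st, p)
    r1 <- reaction_rates(st, p, drug = mod)
    flux <- p$lambda_MT * st[["Ta"]] / (p$K_Talpha + st[["Ta"]]) * st[["M2"]]
    ## the difference of full rates cancels terms ~1e5 times larger than
    ## the switching flux, so allow for the float cancellation error
    expect_equal(r0[["M1"]] - r1[["M1"]], flux / 2, tolerance = 1e-4)
    expect_equal(r1[["M2"]] - r0[["M2"]], flux / 2, tolerance = 1e-4)
  }
})

test_that("anti-TGF-beta blockade rescales the promoting saturation factors", {
  ## with Tb = K_Tb and B = 0.1 each promoting factor becomes
  ## (Tb/1.1)/(K_Tb + Tb/1.1) = 1/2.1
  p <- params_raw()
  p <- set_param(p, "lambda_mfG", 0)
  st <- setNames(rep(0, 14), species_names())
  st["f"] <- 1; st["Tb"] <- p$K_Tbeta
  mod <- drug_modifier(drug_regimen("anti_TGFb", A = 0.1, B = 0.1), t = 200)
  r <- reaction_rates(st, p, drug = mod)
  expect_equal(r[["m"]], p$lambda_mfT / 2.1, tolerance = 1e-12)
  ## untreated reference is the half-saturation point
  expect_equal(reaction_rates(st, p)[["m"]], p$lambda_mfT / 2,
               tolerance = 1e-12)
})

test_that("combinations apply every component simultaneously", {
  reg <- combine_regimens(drug_regimen("anti_TGFb", A = 0.1, B = 0.1),
                          drug_regimen("anti_IL13", B3 = 1))
  mod <- drug_modifier(reg, t = 200)
  expect_equal(mod$A, 1.1)
  expect_equal(mod$B, 1.1)
  expect_equal(mod$TbI13, 2)
  expect_equal(mod$MT, 1)
  mod_half <- drug_modifier(reg, t = 110)   # mid-ramp
  expect_equal(mod_half$A, 1.05)
  expect_equal(mod_half$TbI13, 1.5)
})

test_that("a zero-amplitude regimen reproduces the untreated trajectory bitwise", {
  base_ss <- solve_homeostasis(default_parameters(calibrated = TRUE))
  reg0 <- drug_regimen("anti_TGFb", A = 0, B = 0, start_day = 1)
  sc0 <- make_fixture("tiny-disease", grid = 4, duration = 2, drug = reg0)
  sc1 <- make_fixture("tiny-disease", grid = 4, duration = 2)
  r0 <- simulate(sc0, baseline = base_ss)
  r1 <- simulate(sc1, baseline = base_ss)
  expect_identical(r0$averages, r1$averages)
})

test_that("day-300 ECM is monotone non-increasing in the anti-TGF-beta dose", {
  mild <- treatment_preset("mild")
  base <- scenario(grid = 4, damage = mild$damage, duration = 300,
                   lambda_E0 = mild$lambda_E0, dt_slow = 0.1)
  regs <- list(untreated = NULL,
               A05 = drug_regimen("anti_TGFb", A = 0.05, B = 0.05),
               A10 = drug_regimen("anti_TGFb", A = 0.1, B = 0.1),
               A20 = drug_regimen("anti_TGFb", A = 0.2, B = 0.2))
  tr <- compare_scenarios(base, regs)
  ecm <- tr$endpoints$ecm[match(c("untreated", "A05", "A10", "A20"),
                                tr$endpoints$arm)]
  expect_true(all(diff(ecm) < 0))
  expect_equal(
    tr$endpoints$ecm_vs_untreated[tr$endpoints$arm == "untreated"], 0)
})
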