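test_that("the parameter table is complete and well-formed", {
  tab <- parameter_table()
  expect_true(all(c("name", "value", "unit", "provenance", "description")
                  %in% names(tab)))
  expect_false(anyDuplicated(tab$name) > 0)
  expect_true(all(tab$value >= 0))
  expect_true(all(tab$provenance %in% c("table", "estimated", "unvalued")))
  ## the four constants the equations use but no table values
  unv <- tab$name[tab$provenance == "unvalued"]
  expect_setequal(unv, c("K_D", "lambda_MTalpha", "lambda_TbetaI13",
                         "lambda_S"))
})

test_that("structural invariants are enforced", {
  p <- params_raw()
  expect_silent(validate_parameters(p))
  expect_error(set_param(p, "rho_star", 0.5), "rho_0")
  expect_error(set_param(p, "d_G", -1), "negative")
  expect_error(set_param(p, "no_such_rate", 1), "unknown parameter")
})

test_that("parameter files round-trip and reject unknown keys", {
  p <- default_parameters(calibrated = TRUE)
  path <- tempfile(fileext = ".yaml")
  write_parameters(p, path)
  p2 <- load_parameters(path)
  expect_equal(unlist(p2), unlist(p), tolerance = 1e-15)
  writeLines("lambda_MTT: 1e-3", path)   # misspelled key
  expect_error(load_parameters(path), "lambda_MTT")
  writeLines("lambda_MT: 0", path)
  p3 <- load_parameters(path)
  expect_identical(p3$lambda_MT, 0)
  info <- as.data.frame(p3)
  expect_identical(info$provenance[info$name == "lambda_MT"], "user")
})

test_that("shipped parameter files agree with the in-code defaults", {
  raw_file <- system.file("extdata", "params_table.yaml", package = "fibrosim")
  cal_file <- system.file("extdata", "params_calibrated.yaml",
                          package = "fibrosim")
  expect_true(nzchar(raw_file) && nzchar(cal_file))
  raw <- load_parameters(raw_file)
  expect_equal(unlist(raw), unlist(params_raw()), tolerance = 1e-12)
  cal <- load_parameters(cal_file)
  expect_equal(unlist(cal), unlist(default_parameters(calibrated = TRUE)),
               tolerance = 1e-10)
})
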