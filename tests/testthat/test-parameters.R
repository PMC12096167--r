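test_that("base-case defaults carry the published point estimates", {
  p <- cmpa_parameters()
  expect_identical(p$demographics$population_under_6mo, 312721)
  expect_identical(p$demographics$ebf_fraction, 0.42)
  expect_identical(p$demographics$suspected_incidence, 0.068)
  expect_identical(p$demographics$confirmed_incidence, 0.02)
  expect_identical(p$clinical$ehf_effectiveness, 0.90)
  expect_identical(p$clinical$aaf_effectiveness, 1.00)
  expect_identical(p$clinical$tolerance_cumulative, c("12" = 0.56, "24" = 0.77))
  expect_identical(p$costs$aaf_young, 1426)
  expect_identical(p$costs$aaf_old, 739)
  expect_identical(p$costs$ehf_young, 1170)
  expect_identical(p$costs$ehf_old, 673)
  expect_identical(p$clinical$diagnostic_duration_weeks, 4)
  expect_identical(p$time$horizon_age_months, 24)
  # defaults pass validation unchanged
  expect_silent(validate_cmpa_parameters(p))
})

test_that("the shipped base-case config reproduces the defaults", {
  f <- system.file("extdata", "base_case.yaml", package = "cmpacea")
  expect_equal(read_cmpa_parameters(f), cmpa_parameters())
})

test_that("config round-trips losslessly, including random scenarios", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  p <- cmpa_parameters()
  write_cmpa_parameters(p, tmp)
  expect_equal(read_cmpa_parameters(tmp), p)
  for (q in draw_scenarios(5, seed = 42)) {
    write_cmpa_parameters(q, tmp)
    expect_equal(read_cmpa_parameters(tmp), q, tolerance = 1e-12)
  }
})

test_that("validation names the offending key", {
  expect_error(cmpa_parameters(ebf_fraction = 1.2),
               "ebf_fraction.*out of range")
  expect_error(cmpa_parameters(tolerance_cumulative = c("12" = 0.8, "24" = 0.7)),
               "non-monotone tolerance")
  expect_error(cmpa_parameters(tolerance_cumulative = c("12" = 0.5, "24" = 1.3)),
               "tolerance_cumulative")
  expect_error(cmpa_parameters(confirmed_incidence = 0.1),
               "confirmed_incidence.*exceeds suspected")
  expect_error(cmpa_parameters(ehf_old = -5), "ehf_old")
  expect_error(cmpa_parameters(population_under_6mo = 12.5),
               "population_under_6mo")
  expect_error(cmpa_parameters(days_per_month = 40), "days_per_month")
  expect_error(cmpa_parameters(entry_age_months = 30), "entry_age_months")
  expect_error(cmpa_parameters(nonexistent = 1), "unknown parameter")
})

test_that("config files with unknown or missing keys are rejected", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_cmpa_parameters(cmpa_parameters(), tmp)
  txt <- readLines(tmp)
  writeLines(c(txt, "extras:", "  foo: 1"), tmp)
  expect_error(read_cmpa_parameters(tmp), "unknown config group")
  writeLines(sub("ehf_effectiveness", "ehf_efficacy", txt), tmp)
  expect_error(read_cmpa_parameters(tmp), "unknown key")
  writeLines(txt[!grepl("aaf_young", txt)], tmp)
  expect_error(read_cmpa_parameters(tmp), "missing field.*aaf_young")
})

test_that("AAF-below-eHF prices are allowed (needed by the DSA low endpoints)", {
  expect_silent(validate_cmpa_parameters(cmpa_parameters(aaf_young = 1140)))
})
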