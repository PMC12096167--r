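test_that("default ranges reproduce the published seven rows verbatim", {
  r <- default_dsa_ranges(cmpa_parameters())
  expect_identical(nrow(r), 7L)
  get <- function(name) r[r$parameter == name, c("low", "base", "high")]
  expect_equal(unlist(get("ehf_young"), use.names = FALSE), c(936, 1170, 1404))
  expect_equal(unlist(get("aaf_young"), use.names = FALSE), c(1140, 1426, 1711))
  expect_equal(unlist(get("aaf_old"), use.names = FALSE), c(591, 739, 886))
  expect_equal(unlist(get("ehf_old"), use.names = FALSE), c(539, 673, 808))
  expect_equal(unlist(get("tolerance_24"), use.names = FALSE), c(0.57, 0.77, 0.96))
  expect_equal(unlist(get("tolerance_12"), use.names = FALSE), c(0.40, 0.56, 0.70))
  expect_equal(unlist(get("suspected"), use.names = FALSE), c(11000, 12333, 14000))
})

test_that("a uniform fraction rebuilds ranges around base, clamping probabilities", {
  r <- default_dsa_ranges(cmpa_parameters(), uniform_fraction = 0.25)
  expect_equal(r$low, r$base * 0.75)
  expect_equal(r$high[r$parameter == "ehf_young"], 1170 * 1.25)
  expect_lte(max(r$high[grepl("tolerance", r$parameter)]), 1)
})

test_that("every published endpoint keeps AAF-first dominant", {
  d <- cmpa_dsa(cmpa_parameters())
  expect_identical(nrow(d), 7L)
  expect_true(all(d$label_low == "dominated"))
  expect_true(all(d$label_high == "dominated"))
  # dominated label means positive saving and positive months gained
  expect_true(all(d$outcome_low > 0))
  expect_true(all(d$outcome_high > 0))
})

test_that("the joint worst corner (AAF high, eHF low) stays dominant", {
  p <- cmpa_parameters(aaf_young = 1711, aaf_old = 886,
                       ehf_young = 936, ehf_old = 539)
  fit <- cmpa_cea(p)
  expect_gt(fit$cost_saving, 0)
  expect_gt(fit$months_gained, 0)
  expect_identical(fit$comparison$label, "dominated")
})

test_that("rows are sorted in tornado order with formula costs on top", {
  d <- cmpa_dsa(cmpa_parameters())
  expect_true(all(diff(d$spread) <= 1e-9))
  expect_setequal(d$parameter[1:2], c("aaf_young", "ehf_young"))
})

test_that("a degenerate range has zero spread", {
  r <- data.frame(parameter = "ehf_young", low = 1170, base = 1170, high = 1170)
  d <- cmpa_dsa(cmpa_parameters(), ranges = r)
  expect_equal(d$spread, 0)
})

test_that("an empty range table yields an empty result", {
  r <- default_dsa_ranges(cmpa_parameters())[0, ]
  d <- cmpa_dsa(cmpa_parameters(), ranges = r)
  expect_identical(nrow(d), 0L)
})

test_that("invalid ranges fail naming the parameter", {
  r <- data.frame(parameter = "tolerance_24", low = 0.57, base = 0.77,
                  high = 1.3)
  expect_error(cmpa_dsa(cmpa_parameters(), ranges = r), "tolerance_24")
  r2 <- data.frame(parameter = "ehf_young", low = 2000, base = 1170,
                   high = 1404)
  expect_error(cmpa_dsa(cmpa_parameters(), ranges = r2),
               "low <= base <= high")
  expect_error(cmpa_dsa(cmpa_parameters(), ranges = data.frame(x = 1)),
               "columns")
})

test_that("tornado order is invariant to the sign of the outcome", {
  d_effect <- cmpa_dsa(cmpa_parameters(), outcome = "delta_effect")
  expect_true(all(diff(d_effect$spread) <= 1e-9))
  expect_true(all(d_effect$spread >= 0))
})
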