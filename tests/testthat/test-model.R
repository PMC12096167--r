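test_that("week-to-month conversion follows the calendar convention", {
  expect_equal(weeks_to_months(4, 30.4375), 28 / 30.4375)
  expect_equal(weeks_to_months(4, 30.4375), 0.9199, tolerance = 1e-4)
  expect_identical(weeks_to_months(0, 30.4375), 0)
  expect_identical(weeks_to_months(4, 28), 1)
})

test_that("arm trees carry the expected branch structure and probabilities", {
  p <- cmpa_parameters()
  co <- cohort_breakdown(p)
  tr <- build_arm(p, "eHF_first")
  # challenge-negative exit probability 1 - 0.02/0.068
  neg <- tr$branches[[1]]
  expect_match(neg$label, "ruled out")
  expect_equal(neg$prob, 1 - 0.02 / 0.068, tolerance = 1e-12)
  expect_equal(neg$prob, 0.7059, tolerance = 1e-4)
  # symptomatic-failure branch child count: 12,334 * (0.02/0.068) * 0.10
  paths <- tree_paths(tr)
  fail_paths <- grepl("non-responder", paths$path)
  expect_equal(sum(paths$prob[fail_paths]) * co$suspected,
               12334 * (0.02 / 0.068) * 0.10, tolerance = 1e-9)
  expect_equal(sum(paths$prob[fail_paths]) * co$suspected, 362.8,
               tolerance = 1e-3)
})

test_that("full eHF effectiveness removes the rescue branch", {
  tr <- build_arm(cmpa_parameters(ehf_effectiveness = 1), "eHF_first")
  paths <- tree_paths(tr)
  expect_equal(sum(paths$prob[grepl("non-responder", paths$path)]), 0)
})

test_that("child counts are conserved at every split of both arm trees", {
  p <- cmpa_parameters()
  n <- cohort_breakdown(p)$suspected
  for (arm in c("AAF_first", "eHF_first")) {
    tr <- build_arm(p, arm)
    expect_true(check_conservation(tr, n))
    res <- evaluate_arm(p, arm)
    expect_equal(sum(res$trace$children), n, tolerance = 1e-9)
    expect_true(all(res$trace$children >= 0))
  }
})

test_that("arm totals agree between rollback and the path-enumeration oracle", {
  p <- cmpa_parameters()
  for (arm in c("AAF_first", "eHF_first")) {
    tr <- build_arm(p, arm)
    expect_equal(tree_rollback(tr), paths_expectation(tr), tolerance = 1e-9)
  }
})

test_that("tree-based months gained equals the closed form for any scenario", {
  p <- cmpa_parameters()
  fit <- cmpa_cea(p)
  expect_equal(fit$months_gained, closed_form_months_gained(p),
               tolerance = 1e-6)
  # random scenarios, including reduced AAF effectiveness
  for (q in draw_scenarios(20, seed = 11, cv = 0.15)) {
    q$clinical$aaf_effectiveness <- stats::runif(1, q$clinical$ehf_effectiveness, 1)
    f <- cmpa_cea(q)
    expect_equal(f$months_gained, closed_form_months_gained(q),
                 tolerance = 1e-6)
  }
})

test_that("the effect ceiling and sign constraints hold", {
  fit <- cmpa_cea()
  horizon_span <- fit$params$time$horizon_age_months -
    fit$params$time$entry_age_months
  for (arm in fit$arms) {
    expect_lte(arm$total_effect, fit$cohort$suspected * horizon_span)
    expect_gte(arm$total_effect, 0)
    expect_gte(arm$total_cost, 0)
  }
})

test_that("arm cost is monotone non-decreasing in every monthly price", {
  base <- cmpa_cea()
  for (k in c("aaf_young", "aaf_old", "ehf_young", "ehf_old")) {
    args <- stats::setNames(list(cmpa_parameters()$costs[[k]] * 1.3), k)
    up <- cmpa_cea(do.call(cmpa_parameters, args))
    for (arm in c("AAF_first", "eHF_first")) {
      expect_gte(up$arms[[arm]]$total_cost, base$arms[[arm]]$total_cost)
    }
  }
})

test_that("months gained is non-increasing in eHF effectiveness", {
  gains <- sapply(seq(0.5, 1, by = 0.1), function(e)
    cmpa_cea(cmpa_parameters(ehf_effectiveness = e))$months_gained)
  expect_true(all(diff(gains) <= 1e-9))
})

test_that("tolerance acquisition only ever lowers cost; none maximizes it", {
  p0 <- cmpa_parameters(tolerance_cumulative = c("12" = 0, "24" = 0))
  fit0 <- cmpa_cea(p0)
  base <- cmpa_cea()
  hi <- cmpa_cea(cmpa_parameters(tolerance_cumulative = c("12" = 0.7, "24" = 0.9)))
  for (arm in c("AAF_first", "eHF_first")) {
    expect_gte(fit0$arms[[arm]]$total_cost, base$arms[[arm]]$total_cost)
    expect_gte(base$arms[[arm]]$total_cost, hi$arms[[arm]]$total_cost)
  }
})

test_that("keep-accruing exit semantics only raises effects, never costs", {
  stop_fit <- cmpa_cea()
  keep_fit <- cmpa_cea(cmpa_parameters(tolerance_exit = "keep_accruing"))
  for (arm in c("AAF_first", "eHF_first")) {
    expect_gte(keep_fit$arms[[arm]]$total_effect,
               stop_fit$arms[[arm]]$total_effect)
    expect_equal(keep_fit$arms[[arm]]$total_cost,
                 stop_fit$arms[[arm]]$total_cost)
  }
  # every non-tolerant confirmed child accrues the full entry-to-horizon span
  expect_equal(keep_fit$arms$AAF_first$total_effect,
               stop_fit$cohort$confirmed_expected * (24 - 3), tolerance = 1e-6)
})

test_that("as-fed billing reverses the sign of the cost delta", {
  pub <- cmpa_cea(cmpa_parameters(cost_convention = "published"))
  fed <- cmpa_cea(cmpa_parameters(cost_convention = "as_fed"))
  expect_gt(pub$cost_saving, 0)
  expect_lt(fed$cost_saving, 0)
  # effect side is unaffected by the billing convention
  expect_equal(pub$months_gained, fed$months_gained, tolerance = 1e-9)
  # under as-fed billing AAF-first buys months at a finite ICER
  cmp <- cea_compare(fed$arms$eHF_first, fed$arms$AAF_first)
  expect_false(is.na(cmp$icer))
  expect_gt(cmp$icer, 0)
})
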