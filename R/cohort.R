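#' Derive the analysis cohort from demographic parameters
#'
#' Reproduces the cohort arithmetic of the model: from the national
#' under-6-month population, exclusively breastfed children are removed
#' (truncating the fractional count toward zero, so 42\% of 312,721 gives
#' 131,342), the suspected-CMPA cohort is the remaining children times the
#' suspected incidence rounded half-up (12,334 in the base case), and the
#' expected number of true CMPA cases among the suspected is
#' `suspected * confirmed_incidence / suspected_incidence`, kept fractional
#' — downstream computations use continuous expected child-counts and round
#' only at reporting.
#'
#' When `suspected_override` is set (as in the sensitivity analysis row that
#' varies the symptomatic cohort size directly) it replaces the derived
#' suspected count; the confirmed expectation still uses the incidence ratio.
#'
#' @param params a `cmpa_parameters` object, or a bare `demographics` list.
#' @return An object of class `cmpa_cohort`: list with `total`,
#'   `exclusively_breastfed`, `eligible`, `suspected`, `confirmed_expected`,
#'   and `p_confirmed` (the conditional probability of confirmation among
#'   suspected, `confirmed_incidence / suspected_incidence`).
#' @examples
#' cohort_breakdown(cmpa_parameters())
#' @export
cohort_breakdown <- function(params) {
  d <- if (inherits(params, "cmpa_parameters")) params$demographics else params
  total <- d$population_under_6mo
  ebf <- trunc(total * d$ebf_fraction)
  eligible <- total - ebf
  if (d$suspected_incidence == 0 && d$confirmed_incidence > 0)
    fail("suspected_incidence: zero with positive confirmed_incidence, ",
         "confirmation probability undefined")
  p_conf <- if (d$suspected_incidence == 0) 0 else
    d$confirmed_incidence / d$suspected_incidence
  suspected <- if (!is.null(d$suspected_override)) d$suspected_override else
    round_half_up(eligible * d$suspected_incidence)
  structure(list(
    total = total,
    exclusively_breastfed = ebf,
    eligible = eligible,
    suspected = suspected,
    confirmed_expected = suspected * p_conf,
    p_confirmed = p_conf
  ), class = "cmpa_cohort")
}

#' @export
print.cmpa_cohort <- function(x, ...) {
  cat("CMPA model cohort\n")
  cat(sprintf("  population under 6 months : %s\n", format(x$total, big.mark = ",")))
  cat(sprintf("  exclusively breastfed     : %s (excluded)\n",
              format(x$exclusively_breastfed, big.mark = ",")))
  cat(sprintf("  formula-eligible          : %s\n", format(x$eligible, big.mark = ",")))
  cat(sprintf("  suspected CMPA (cohort)   : %s\n", format(x$suspected, big.mark = ",")))
  cat(sprintf("  expected confirmed CMPA   : %s (P(confirmed | suspected) = %.4f)\n",
              format(round(x$confirmed_expected, 1), big.mark = ","), x$p_confirmed))
  invisible(x)
}

#' @export
as.data.frame.cmpa_cohort <- function(x, ...) {
  data.frame(total = x$total,
             exclusively_breastfed = x$exclusively_breastfed,
             eligible = x$eligible,
             suspected = x$suspected,
             confirmed_expected = x$confirmed_expected,
             p_confirmed = x$p_confirmed)
}
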