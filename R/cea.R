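#' Incremental cost-effectiveness comparison
#'
#' Compares a comparator strategy `b` against a reference `a` computed under
#' identical parameters: `delta_cost = cost(b) - cost(a)`,
#' `delta_effect = effect(b) - effect(a)`. When the signs make a ratio
#' meaningless the result is a dominance label instead of an ICER:
#' `"dominated"` if `b` is costlier *and* less effective, `"dominant"` if
#' `b` is cheaper *and* more effective. With a zero effect difference and a
#' nonzero cost difference the ICER is undefined
#' (`"cost-difference only, ICER undefined"`); with both deltas zero the
#' strategies are `"equivalent"`. Otherwise
#' `icer = delta_cost / delta_effect` in USD per symptom-free month.
#'
#' @param a reference strategy: a `cmpa_arm`, or any list with `total_cost`
#'   and `total_effect`.
#' @param b comparator strategy, same form.
#' @return An object of class `cea_result`: list with `reference`,
#'   `comparator`, `delta_cost`, `delta_effect`, `icer` (NA when a dominance
#'   or undefined label applies) and `label`.
#' @examples
#' cea_compare(list(total_cost = 100, total_effect = 10),
#'             list(total_cost = 200, total_effect = 12))  # ICER 50
#' @export
cea_compare <- function(a, b) {
  dc <- b$total_cost - a$total_cost
  de <- b$total_effect - a$total_effect
  icer <- NA_real_
  if (dc > 0 && de < 0) {
    label <- "dominated"
  } else if (dc < 0 && de > 0) {
    label <- "dominant"
  } else if (de == 0 && dc != 0) {
    label <- "cost-difference only, ICER undefined"
  } else if (de == 0 && dc == 0) {
    label <- "equivalent"
  } else {
    icer <- dc / de
    label <- sprintf("ICER %.2f USD per symptom-free month", icer)
  }
  structure(list(reference = if (!is.null(a$arm)) a$arm else "reference",
                 comparator = if (!is.null(b$arm)) b$arm else "comparator",
                 delta_cost = dc, delta_effect = de,
                 icer = icer, label = label),
            class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("Incremental comparison: %s vs %s (reference)\n",
              x$comparator, x$reference))
  cat(sprintf("  incremental cost   : %s USD\n",
              format(round(x$delta_cost, 2), big.mark = ",")))
  cat(sprintf("  incremental effect : %s symptom-free months\n",
              format(round(x$delta_effect, 2), big.mark = ",")))
  cat(sprintf("  result             : %s\n", x$label))
  invisible(x)
}

#' Strategy comparison table (both orientations)
#'
#' Renders the two-arm analysis as a table in the conventional layout —
#' cost, avoided cost, symptom-free months, months gained, ICER/dominance —
#' from the chosen reference arm. Printed both ways the dominance reading is
#' unambiguous: with AAF-first as reference the eHF-first row shows the
#' avoided cost and the negative months difference and the label
#' "dominated".
#'
#' @param fit a `cmpa_cea` object.
#' @param reference which arm anchors the incremental columns.
#' @return A data.frame with one row per strategy.
#' @export
cea_table <- function(fit, reference = c("AAF_first", "eHF_first")) {
  reference <- match.arg(reference)
  other <- setdiff(c("AAF_first", "eHF_first"), reference)
  ref <- fit$arms[[reference]]; cmp <- fit$arms[[other]]
  res <- cea_compare(ref, cmp)
  data.frame(
    formula = c(sub("_first", "", reference), sub("_first", "", other)),
    cost_usd = c(ref$total_cost, cmp$total_cost),
    avoided_cost = c(0, max(res$delta_cost, 0)),
    months_without_symptoms = c(ref$total_effect, cmp$total_effect),
    months_gained = c(0, res$delta_effect),
    icer = c("", res$label),
    stringsAsFactors = FALSE)
}
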