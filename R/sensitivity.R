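#' Default one-way sensitivity ranges
#'
#' The seven published one-way ranges: the four monthly formula costs varied
#' ±20\% around their base prices, the two cumulative tolerance
#' probabilities varied ±25\% (with the published rounding of the
#' endpoints), and the suspected-cohort size varied across its published
#' 11,000–14,000 bounds (the published base for that row, 12,333, is the
#' unrounded cohort product rounded down). Endpoints are taken verbatim from
#' the published table rather than recomputed, so e.g. the eHF young-band
#' low endpoint is 936 = 1,170 − 20\%.
#'
#' With `uniform_fraction` set (e.g. 0.25) every row instead uses
#' `base * (1 ∓ fraction)`, probabilities clamped to \[0, 1\] — the strict
#' uniform-±25\% reading of the published text.
#'
#' @param params a `cmpa_parameters` object supplying the base values.
#' @param uniform_fraction optional single relative half-width overriding
#'   the published endpoints.
#' @return A data.frame with columns `parameter`, `label`, `low`, `base`,
#'   `high`.
#' @examples
#' default_dsa_ranges(cmpa_parameters())
#' @export
default_dsa_ranges <- function(params = cmpa_parameters(),
                               uniform_fraction = NULL) {
  co <- params$costs
  tol <- params$clinical$tolerance_cumulative
  suspected_base <- floor(cohort_breakdown(params)$eligible *
                          params$demographics$suspected_incidence)
  r <- data.frame(
    parameter = c("ehf_young", "aaf_young", "aaf_old", "ehf_old",
                  "tolerance_24", "tolerance_12", "suspected"),
    label = c(
      "Monthly cost of eHF in infants under 1 year of age",
      "Monthly cost of AAF in infants under 1 year of age",
      "Monthly cost of AAF in infants older than 1 year of age",
      "Monthly cost of eHF in infants older than 1 year of age",
      "Tolerance to cow's milk at 24 months of age",
      "Tolerance to cow's milk at 12 months of age",
      "6 months of age with CMPA-like symptoms"),
    low  = c( 936, 1140, 591, 539, 0.57, 0.40, 11000),
    base = c(co$ehf_young, co$aaf_young, co$aaf_old, co$ehf_old,
             tol[["24"]], tol[["12"]], suspected_base),
    high = c(1404, 1711, 886, 808, 0.96, 0.70, 14000),
    stringsAsFactors = FALSE)
  if (!is.null(uniform_fraction)) {
    stopifnot(uniform_fraction > 0, uniform_fraction < 1)
    r$low <- r$base * (1 - uniform_fraction)
    r$high <- r$base * (1 + uniform_fraction)
    probs <- grepl("^tolerance", r$parameter)
    r$high[probs] <- pmin(r$high[probs], 1)
  }
  r
}

# apply one DSA parameter setting, dispatching on the range's parameter name
dsa_set <- function(params, name, value) {
  switch(name,
    tolerance_12 = {
      tol <- params$clinical$tolerance_cumulative
      tol[["12"]] <- value
      set_cmpa_parameters(params, tolerance_cumulative = tol)
    },
    tolerance_24 = {
      tol <- params$clinical$tolerance_cumulative
      tol[["24"]] <- value
      set_cmpa_parameters(params, tolerance_cumulative = tol)
    },
    suspected = set_cmpa_parameters(params, suspected_override = value),
    do.call(set_cmpa_parameters,
            c(list(params), stats::setNames(list(value), name)))
  )
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-evaluates both strategy arms at each range's low and high endpoint
#' with all other parameters held at base, records the chosen incremental
#' outcome and the dominance classification of the eHF-first arm at each
#' endpoint, and orders the rows by descending absolute spread (tornado
#' order). A range endpoint that violates a parameter invariant (e.g. a
#' tolerance above 1) fails with a message naming the parameter.
#'
#' @param params a `cmpa_parameters` object (base case).
#' @param ranges a data.frame as returned by [default_dsa_ranges()]; columns
#'   `parameter`, `low`, `base`, `high` (and optionally `label`).
#' @param outcome incremental outcome to tabulate: `"delta_cost"` (cost of
#'   eHF-first minus AAF-first, i.e. the AAF-first saving), `"delta_effect"`
#'   (symptom-free months of eHF-first minus AAF-first) or `"icer"`.
#' @return An object of class `cmpa_dsa`: data.frame with columns
#'   `parameter`, `label`, `low`, `base`, `high`, `outcome_low`,
#'   `outcome_high`, `spread`, `label_low`, `label_high`, sorted by
#'   descending `spread`.
#' @examples
#' cmpa_dsa(cmpa_parameters())
#' @export
cmpa_dsa <- function(params = cmpa_parameters(),
                     ranges = default_dsa_ranges(params),
                     outcome = c("delta_cost", "delta_effect", "icer")) {
  outcome <- match.arg(outcome)
  params <- validate_cmpa_parameters(params)
  needed <- c("parameter", "low", "base", "high")
  if (!is.data.frame(ranges) || !all(needed %in% names(ranges)))
    fail("ranges: must be a data.frame with columns ",
         paste(needed, collapse = ", "))
  if (nrow(ranges) &&
      any(ranges$low > ranges$base + 1e-9 | ranges$base > ranges$high + 1e-9)) {
    bad <- ranges$parameter[ranges$low > ranges$base + 1e-9 |
                            ranges$base > ranges$high + 1e-9][1]
    fail("range for ", bad, ": requires low <= base <= high")
  }
  eval_at <- function(name, value) {
    p <- tryCatch(dsa_set(params, name, value),
                  error = function(e) fail("range for ", name, ": ",
                                           conditionMessage(e)))
    fit <- cmpa_cea(p)
    list(outcome = switch(outcome,
                          delta_cost = fit$comparison$delta_cost,
                          delta_effect = fit$comparison$delta_effect,
                          icer = fit$comparison$icer),
         label = fit$comparison$label)
  }
  rows <- lapply(seq_len(nrow(ranges)), function(i) {
    lo <- eval_at(ranges$parameter[i], ranges$low[i])
    hi <- eval_at(ranges$parameter[i], ranges$high[i])
    data.frame(parameter = ranges$parameter[i],
               label = if ("label" %in% names(ranges)) ranges$label[i]
                       else ranges$parameter[i],
               low = ranges$low[i], base = ranges$base[i],
               high = ranges$high[i],
               outcome_low = if (is.null(lo$outcome)) NA_real_ else lo$outcome,
               outcome_high = if (is.null(hi$outcome)) NA_real_ else hi$outcome,
               label_low = lo$label, label_high = hi$label,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(parameter = character(0), label = character(0),
                      low = numeric(0), base = numeric(0), high = numeric(0),
                      outcome_low = numeric(0), outcome_high = numeric(0),
                      label_low = character(0), label_high = character(0),
                      spread = numeric(0))
  } else {
    out$spread <- abs(out$outcome_high - out$outcome_low)
    out <- out[order(-out$spread), ]
    rownames(out) <- NULL
  }
  structure(out, class = c("cmpa_dsa", "data.frame"),
            outcome = outcome)
}

#' @export
print.cmpa_dsa <- function(x, ...) {
  cat(sprintf("One-way sensitivity analysis (outcome: %s; tornado order)\n",
              attr(x, "outcome")))
  df <- as.data.frame(x)
  df$outcome_low <- round(df$outcome_low, 2)
  df$outcome_high <- round(df$outcome_high, 2)
  df$spread <- round(df$spread, 2)
  print(df[, c("label", "low", "base", "high",
               "outcome_low", "outcome_high", "spread",
               "label_low", "label_high")], row.names = FALSE)
  invisible(x)
}
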