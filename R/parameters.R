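#' Model parameters for the CMPA formula-strategy model
#'
#' Constructs and validates the full parameter set of the cost-effectiveness
#' model: national demographics, clinical probabilities, monthly formula
#' costs, and the time conventions of the 24-month follow-up. Called with no
#' arguments it returns the base case: the 2019 Argentine birth-cohort
#' demographics, 90\%/100\% eHF/AAF effectiveness, cumulative cow's-milk
#' tolerance of 56\% at 12 and 77\% at 24 months, and the four monthly
#' formula prices in 2024 USD.
#'
#' @details
#' The parameter object is a nested list of four groups mirroring how a
#' scenario is written down in a config file:
#'
#' \describe{
#'   \item{`demographics`}{`population_under_6mo` (count), `ebf_fraction`
#'     (exclusively breastfed, excluded from the cohort), `mixed_fraction`
#'     (carried for audit; mixed-fed children are costed as formula-fed,
#'     scaled by `mixed_formula_share`), `suspected_incidence`,
#'     `confirmed_incidence`, and an optional `suspected_override` used by
#'     the sensitivity analysis to set the suspected-cohort size directly.}
#'   \item{`clinical`}{`ehf_effectiveness`, `aaf_effectiveness` (probability
#'     that a true-CMPA child is asymptomatic on each formula),
#'     `tolerance_cumulative` (named vector, age in months to cumulative
#'     probability of cow's-milk tolerance), `diagnostic_duration_weeks`,
#'     `challenge_interval_months`.}
#'   \item{`costs`}{`aaf_young`, `aaf_old`, `ehf_young`, `ehf_old` — monthly
#'     USD prices in the young/old age band — and `age_band_switch_months`,
#'     the age at which the cheaper old-band price applies (default 9 months,
#'     when half the energy intake comes from complementary food).}
#'   \item{`time`}{`entry_age_months` (default 3, the midpoint of the
#'     "under 6 months" entry window), `horizon_age_months` (24),
#'     `days_per_month` (365.25/12, used to convert the 4-week diagnostic
#'     phase to 0.92 months).}
#'   \item{`conventions`}{`tolerance_exit`: `"stop"` (a child who acquires
#'     tolerance exits the model — stops accruing both cost and symptom-free
#'     months) or `"keep_accruing"` (formula cost stops, effect accrues to the
#'     horizon). `cost_convention`: `"published"` or `"as_fed"` — see the
#'     methods vignette; `"published"` reproduces the reported strategy
#'     totals, `"as_fed"` bills each arm for the formula it actually feeds
#'     during the diagnostic phase.}
#' }
#'
#' The printed source table gives the under-6-month population as both
#' 3,12,720 and 312,721; the value used in the published cohort arithmetic
#' (312,721) is adopted.
#'
#' @param ... named overrides of any leaf field, e.g.
#'   `cmpa_parameters(ehf_effectiveness = 0.95, ehf_young = 1000)`.
#' @return A validated object of class `cmpa_parameters`.
#' @seealso [read_cmpa_parameters()], [write_cmpa_parameters()],
#'   [cohort_breakdown()], [cmpa_cea()]
#' @examples
#' p <- cmpa_parameters()
#' p$clinical$ehf_effectiveness
#' p2 <- cmpa_parameters(ehf_effectiveness = 0.95)
#' @export
cmpa_parameters <- function(...) {
  p <- structure(list(
    demographics = list(
      population_under_6mo = 312721,
      ebf_fraction         = 0.42,
      mixed_fraction       = 0.46,
      suspected_incidence  = 0.068,
      confirmed_incidence  = 0.02,
      mixed_formula_share  = 1.0,
      suspected_override   = NULL
    ),
    clinical = list(
      ehf_effectiveness         = 0.90,
      aaf_effectiveness         = 1.00,
      tolerance_cumulative      = c("12" = 0.56, "24" = 0.77),
      diagnostic_duration_weeks = 4,
      challenge_interval_months = 6
    ),
    costs = list(
      aaf_young = 1426,
      aaf_old   = 739,
      ehf_young = 1170,
      ehf_old   = 673,
      age_band_switch_months = 9
    ),
    time = list(
      entry_age_months   = 3,
      horizon_age_months = 24,
      days_per_month     = 365.25 / 12
    ),
    conventions = list(
      tolerance_exit  = "stop",
      cost_convention = "published"
    )
  ), class = "cmpa_parameters")
  set_cmpa_parameters(p, ...)
}

#' Modify parameter leaves by name
#'
#' Returns a copy of `params` with the named leaf fields replaced and the
#' result re-validated. Leaf names are unique across groups so no group
#' prefix is needed.
#'
#' @param params a `cmpa_parameters` object.
#' @param ... named leaf values, e.g. `ehf_young = 936`.
#' @return A validated `cmpa_parameters` object.
#' @export
set_cmpa_parameters <- function(params, ...) {
  dots <- list(...)
  if (length(dots)) {
    nm <- names(dots)
    if (is.null(nm) || any(nm == "")) fail("all overrides must be named")
    for (i in seq_along(dots)) {
      hit <- FALSE
      for (grp in names(params)) {
        if (nm[i] %in% names(params[[grp]])) {
          params[[grp]][[nm[i]]] <- dots[[i]]
          hit <- TRUE
          break
        }
      }
      if (!hit) fail("unknown parameter: ", nm[i])
    }
  }
  validate_cmpa_parameters(params)
}

#' Validate a parameter object
#'
#' Checks every invariant of the parameter set and returns the object
#' invisibly unchanged, or fails with a message naming the offending key.
#' Bounds enforced: all proportions in \[0, 1\] with
#' `ebf_fraction + mixed_fraction <= 1` and
#' `confirmed_incidence <= suspected_incidence` (a confirmed case must first
#' be suspected); a positive integer population; a non-decreasing cumulative
#' tolerance map valued in \[0, 1\]; strictly positive costs and durations;
#' `entry_age_months < horizon_age_months`; `days_per_month` in \[28, 31\].
#'
#' Note the relative ordering of AAF and eHF prices is a base-case property,
#' not an invariant: the one-way sensitivity ranges legitimately push the
#' AAF young-band price below the eHF base price.
#'
#' @param params a `cmpa_parameters` object (or plain list with the same
#'   structure).
#' @return `params`, invisibly, with class `cmpa_parameters`.
#' @export
validate_cmpa_parameters <- function(params) {
  d <- params$demographics; cl <- params$clinical
  co <- params$costs; tm <- params$time; cv <- params$conventions

  if (!is_count(d$population_under_6mo) || d$population_under_6mo <= 0)
    fail("population_under_6mo: must be a positive integer count")
  for (k in c("ebf_fraction", "mixed_fraction", "suspected_incidence",
              "confirmed_incidence", "mixed_formula_share")) {
    if (!is_prob(d[[k]])) fail(k, ": proportion out of range [0, 1]")
  }
  if (d$ebf_fraction + d$mixed_fraction > 1 + 1e-12)
    fail("ebf_fraction + mixed_fraction: exceeds 1")
  if (d$confirmed_incidence > d$suspected_incidence)
    fail("confirmed_incidence: exceeds suspected_incidence")
  if (!is.null(d$suspected_override) &&
      (!is_pos(d$suspected_override)))
    fail("suspected_override: must be a positive count or NULL")

  for (k in c("ehf_effectiveness", "aaf_effectiveness")) {
    if (!is_prob(cl[[k]])) fail(k, ": proportion out of range [0, 1]")
  }
  tol <- cl$tolerance_cumulative
  if (is.null(names(tol)) || anyNA(suppressWarnings(as.numeric(names(tol)))))
    fail("tolerance_cumulative: ages must be numeric names")
  ages <- as.numeric(names(tol))
  tol <- tol[order(ages)]
  if (any(tol < 0 | tol > 1))
    fail("tolerance_cumulative: probabilities out of range [0, 1]")
  if (is.unsorted(tol, strictly = FALSE))
    fail("tolerance_cumulative: non-monotone tolerance map")
  params$clinical$tolerance_cumulative <- tol
  if (!is_pos(cl$diagnostic_duration_weeks) &&
      !(is.numeric(cl$diagnostic_duration_weeks) &&
        cl$diagnostic_duration_weeks == 0))
    fail("diagnostic_duration_weeks: must be >= 0")
  if (cl$diagnostic_duration_weeks < 0)
    fail("diagnostic_duration_weeks: must be >= 0")
  if (!is_pos(cl$challenge_interval_months))
    fail("challenge_interval_months: must be > 0")

  for (k in c("aaf_young", "aaf_old", "ehf_young", "ehf_old")) {
    if (!is_pos(co[[k]])) fail(k, ": monthly cost must be > 0")
  }
  if (!is_pos(co$age_band_switch_months))
    fail("age_band_switch_months: must be > 0")

  if (!is_pos(tm$entry_age_months))
    fail("entry_age_months: must be > 0")
  if (tm$entry_age_months >= tm$horizon_age_months)
    fail("entry_age_months: must be below horizon_age_months")
  if (!is.numeric(tm$days_per_month) || tm$days_per_month < 28 ||
      tm$days_per_month > 31)
    fail("days_per_month: must lie in [28, 31]")

  if (!cv$tolerance_exit %in% c("stop", "keep_accruing"))
    fail("tolerance_exit: must be 'stop' or 'keep_accruing'")
  if (!cv$cost_convention %in% c("published", "as_fed"))
    fail("cost_convention: must be 'published' or 'as_fed'")

  class(params) <- "cmpa_parameters"
  invisible(params)
}

.param_schema <- list(
  demographics = c("population_under_6mo", "ebf_fraction", "mixed_fraction",
                   "suspected_incidence", "confirmed_incidence",
                   "mixed_formula_share", "suspected_override"),
  clinical     = c("ehf_effectiveness", "aaf_effectiveness",
                   "tolerance_cumulative", "diagnostic_duration_weeks",
                   "challenge_interval_months"),
  costs        = c("aaf_young", "aaf_old", "ehf_young", "ehf_old",
                   "age_band_switch_months"),
  time         = c("entry_age_months", "horizon_age_months",
                   "days_per_month"),
  conventions  = c("tolerance_exit", "cost_convention")
)

#' Read a scenario from a YAML config file
#'
#' Parses the two-level YAML schema documented in [cmpa_parameters()],
#' rejects unknown groups or keys, and validates every invariant. The
#' shipped base case is at
#' `system.file("extdata", "base_case.yaml", package = "cmpacea")`.
#'
#' @param path path to a YAML file.
#' @return A validated `cmpa_parameters` object.
#' @examples
#' p <- read_cmpa_parameters(
#'   system.file("extdata", "base_case.yaml", package = "cmpacea"))
#' p$costs$ehf_old
#' @export
read_cmpa_parameters <- function(path) {
  if (!file.exists(path)) fail("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) fail("config must be a mapping of parameter groups")
  extra <- setdiff(names(raw), names(.param_schema))
  if (length(extra)) fail("unknown config group: ", extra[1])
  p <- unclass(cmpa_parameters())
  for (grp in names(raw)) {
    bad <- setdiff(names(raw[[grp]]), .param_schema[[grp]])
    if (length(bad)) fail("unknown key in ", grp, ": ", bad[1])
    missing <- setdiff(.param_schema[[grp]],
                       c(names(raw[[grp]]), "suspected_override"))
    if (length(missing)) fail("missing field in ", grp, ": ", missing[1])
    for (k in names(raw[[grp]])) {
      v <- raw[[grp]][[k]]
      if (k == "tolerance_cumulative") v <- unlist(v)
      p[[grp]][[k]] <- v
    }
  }
  validate_cmpa_parameters(structure(p, class = "cmpa_parameters"))
}

#' Write a scenario to a YAML config file
#'
#' Inverse of [read_cmpa_parameters()]: the round trip
#' `read_cmpa_parameters(write_cmpa_parameters(p, f))` restores `p` exactly.
#'
#' @param params a `cmpa_parameters` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cmpa_parameters <- function(params, path) {
  params <- validate_cmpa_parameters(params)
  out <- lapply(unclass(params), function(grp) {
    grp <- grp[!vapply(grp, is.null, logical(1))]
    lapply(grp, function(v) if (length(names(v)) > 1L) as.list(v) else v)
  })
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @export
print.cmpa_parameters <- function(x, ...) {
  d <- x$demographics; cl <- x$clinical; co <- x$costs; tm <- x$time
  cat("CMPA formula-strategy model parameters\n")
  cat(sprintf("  population < 6 mo: %s   EBF %.0f%%   suspected %.1f%%   confirmed %.1f%%\n",
              format(d$population_under_6mo, big.mark = ","),
              100 * d$ebf_fraction, 100 * d$suspected_incidence,
              100 * d$confirmed_incidence))
  cat(sprintf("  effectiveness: eHF %.0f%%, AAF %.0f%%   tolerance: %s\n",
              100 * cl$ehf_effectiveness, 100 * cl$aaf_effectiveness,
              paste(sprintf("%s mo %.0f%%", names(cl$tolerance_cumulative),
                            100 * cl$tolerance_cumulative), collapse = ", ")))
  cat(sprintf("  monthly cost USD: AAF %s/%s, eHF %s/%s (band switch at %g mo)\n",
              co$aaf_young, co$aaf_old, co$ehf_young, co$ehf_old,
              co$age_band_switch_months))
  cat(sprintf("  entry %g mo, horizon %g mo, diagnostic phase %g wk; %s costing, %s exits\n",
              tm$entry_age_months, tm$horizon_age_months,
              cl$diagnostic_duration_weeks,
              x$conventions$cost_convention, x$conventions$tolerance_exit))
  invisible(x)
}
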