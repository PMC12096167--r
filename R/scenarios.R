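#' Draw synthetic parameter scenarios
#'
#' Seeded random parameter sets with the statistical structure of the base
#' case, for property testing and probabilistic exploration. Probabilities
#' are drawn from beta distributions parameterized by their mean (the base
#' value) and a concentration `kappa` (`shape1 = mean * kappa`,
#' `shape2 = (1 - mean) * kappa`); monthly costs from gamma distributions
#' parameterized by mean and coefficient of variation
#' (`shape = 1/cv^2, rate = shape/mean`). Structural constraints hold by
#' construction: the confirmed incidence is drawn as the suspected incidence
#' times a beta-distributed confirmation ratio (so confirmed never exceeds
#' suspected), the tolerance pair is drawn jointly and sorted to keep the
#' cumulative map monotone, and the breastfeeding fractions are redrawn on
#' the rare event their sum exceeds 1. The AAF effectiveness is kept at its
#' base value (a beta with mean 1 is degenerate). Every draw passes full
#' parameter validation; the same seed reproduces the same draws.
#'
#' An infinite `concentration` together with `cv = 0` collapses every draw
#' to the base case (the degenerate limit).
#'
#' @param n_draws number of parameter sets.
#' @param seed RNG seed (the draw is run under [withr]-free local RNG state:
#'   the global seed is saved and restored).
#' @param base a `cmpa_parameters` object giving the distribution means.
#' @param concentration beta concentration for probability parameters
#'   (larger = tighter around base; default 100).
#' @param cv coefficient of variation for cost parameters (default 0.2;
#'   must be > 0 unless infinite concentration collapse is requested with
#'   `cv = 0`).
#' @return A list of `n_draws` validated `cmpa_parameters` objects.
#' @examples
#' draws <- draw_scenarios(5, seed = 1)
#' sapply(draws, function(p) p$clinical$ehf_effectiveness)
#' @export
draw_scenarios <- function(n_draws, seed, base = cmpa_parameters(),
                           concentration = 100, cv = 0.2) {
  stopifnot(is_count(n_draws), n_draws >= 0)
  if (!is.numeric(concentration) || concentration <= 0)
    fail("concentration: must be > 0")
  degenerate <- is.infinite(concentration) && cv == 0
  if (!degenerate && (!is.numeric(cv) || cv <= 0))
    fail("cv: must be > 0")
  base <- validate_cmpa_parameters(base)

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  rbeta_mean <- function(n, mean, kappa) {
    if (is.infinite(kappa) || mean <= 0 || mean >= 1) return(rep(mean, n))
    stats::rbeta(n, mean * kappa, (1 - mean) * kappa)
  }
  rgamma_mean <- function(n, mean, cv) {
    if (cv == 0) return(rep(mean, n))
    shape <- 1 / cv^2
    stats::rgamma(n, shape = shape, rate = shape / mean)
  }

  d <- base$demographics; cl <- base$clinical; co <- base$costs
  ratio_base <- if (d$suspected_incidence > 0)
    d$confirmed_incidence / d$suspected_incidence else 0

  lapply(seq_len(n_draws), function(i) {
    repeat {
      ebf <- rbeta_mean(1, d$ebf_fraction, concentration)
      mixed <- rbeta_mean(1, d$mixed_fraction, concentration)
      if (ebf + mixed <= 1) break
    }
    suspected <- rbeta_mean(1, d$suspected_incidence, concentration)
    ratio <- rbeta_mean(1, ratio_base, concentration)
    tol <- sort(c(rbeta_mean(1, cl$tolerance_cumulative[["12"]], concentration),
                  rbeta_mean(1, cl$tolerance_cumulative[["24"]], concentration)))
    names(tol) <- names(cl$tolerance_cumulative)
    set_cmpa_parameters(
      base,
      ebf_fraction = ebf,
      mixed_fraction = mixed,
      suspected_incidence = suspected,
      confirmed_incidence = ratio * suspected,
      ehf_effectiveness = rbeta_mean(1, cl$ehf_effectiveness, concentration),
      tolerance_cumulative = tol,
      aaf_young = rgamma_mean(1, co$aaf_young, cv),
      aaf_old   = rgamma_mean(1, co$aaf_old, cv),
      ehf_young = rgamma_mean(1, co$ehf_young, cv),
      ehf_old   = rgamma_mean(1, co$ehf_old, cv))
  })
}

#' Simulate the incremental result over random scenarios
#'
#' Draws `nsim` synthetic scenarios around the fitted model's parameters
#' ([draw_scenarios()]) and re-evaluates both arms for each, returning the
#' incremental outcomes — a light probabilistic exploration of the
#' deterministic model.
#'
#' @param object a `cmpa_cea` fit.
#' @param nsim number of scenario draws.
#' @param seed RNG seed (required for reproducibility).
#' @param ... passed to [draw_scenarios()] (`concentration`, `cv`).
#' @return A data.frame with one row per draw: `cost_saving`,
#'   `months_gained`, `label` and `aaf_dominant` (TRUE when AAF-first is
#'   cheaper and more effective).
#' @examples
#' fit <- cmpa_cea()
#' sim <- simulate(fit, nsim = 10, seed = 1)
#' mean(sim$aaf_dominant)
#' @export
simulate.cmpa_cea <- function(object, nsim = 1, seed = 1, ...) {
  draws <- draw_scenarios(nsim, seed = seed, base = object$params, ...)
  rows <- lapply(draws, function(p) {
    fit <- cmpa_cea(p)
    data.frame(cost_saving = fit$cost_saving,
               months_gained = fit$months_gained,
               label = fit$comparison$label,
               aaf_dominant = fit$cost_saving > 0 && fit$months_gained > 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
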