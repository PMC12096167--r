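#' Monthly formula energy requirement
#'
#' The monthly energy a formula-fed infant needs, from the 50th-percentile
#' weight and the age-specific energy requirement:
#' `weight_kg * kcal_per_kg_day * days`. At 6 months the reference male
#' infant (8 kg, 78 kcal/kg/day, 30-day month) needs 18,720 kcal; at
#' 9 months (9 kg, 77 kcal/kg/day) 20,790 kcal.
#'
#' These equations document how the monthly can counts behind the price
#' table arise; the model itself consumes monthly USD prices directly, since
#' per-can prices are not part of the scenario.
#'
#' @param weight_kg 50th-percentile body weight in kg.
#' @param kcal_per_kg_day energy requirement in kcal per kg per day.
#' @param days days in the consumption month (30 in the published equations).
#' @return Energy in kcal per month.
#' @examples
#' monthly_energy(8, 78)   # 18,720 kcal at 6 months
#' monthly_energy(9, 77)   # 20,790 kcal at 9 months
#' @export
monthly_energy <- function(weight_kg, kcal_per_kg_day, days = 30) {
  stopifnot(weight_kg > 0, kcal_per_kg_day > 0, days > 0)
  weight_kg * kcal_per_kg_day * days
}

#' Whole formula cans consumed per month
#'
#' Converts a monthly energy requirement into a whole-can count:
#' `round_half_up(energy * formula_share / kcal_per_can)`. The
#' `formula_share` is the fraction of energy supplied by formula — 1 for an
#' exclusively formula-fed 6-month-old, 0.5 at 9 months when complementary
#' feeding covers half the intake. Rounding is half-up to the nearest whole
#' can: 18,720/1,864 = 10.04 gives 10 cans and 20,790/1,864 × 0.5 = 5.58
#' gives 6 — the only simple rounding rule consistent with both published
#' counts (floor fails the second, ceiling the first).
#'
#' @param energy kcal consumed per month (see [monthly_energy()]).
#' @param kcal_per_can energy content of one can (1,864 kcal for the
#'   reference can).
#' @param formula_share fraction of energy from formula, in (0, 1].
#' @return Integer number of cans per month.
#' @examples
#' cans_per_month(18720)            # 10
#' cans_per_month(20790, formula_share = 0.5)  # 6
#' @export
cans_per_month <- function(energy, kcal_per_can = 1864, formula_share = 1) {
  if (!is_pos(kcal_per_can)) fail("kcal_per_can: must be > 0")
  stopifnot(energy >= 0, formula_share > 0, formula_share <= 1)
  round_half_up(energy * formula_share / kcal_per_can)
}
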