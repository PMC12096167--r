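---
title: "Methods: the CMPA formula-strategy cost-effectiveness model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the CMPA formula-strategy cost-effectiveness model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmpacea)
```

## The decision problem

Cow's-milk protein allergy (CMPA) is the most common food allergy of
infancy. Its non-IgE-mediated forms are diagnosed by an elimination diet
followed by a supervised challenge test: the child is switched to a
hypoallergenic formula for about four weeks; if symptoms resolve and recur
on re-exposure, CMPA is confirmed. Two formula classes are available for
the elimination phase. Extensively hydrolyzed formulas (eHF) are cheaper
but fail to control symptoms in roughly 10% of true CMPA cases;
amino-acid-based formulas (AAF) control essentially all cases but cost
more per month.

The model compares two diagnostic strategies for a cohort of suspected-CMPA
infants followed to 24 months of age:

* **eHF-first** (standard of care): elimination phase on eHF; children
  still symptomatic after the phase — which includes the eHF
  non-responders among the true CMPA cases — receive one additional
  diagnostic period on AAF before their challenge test.
* **AAF-first**: elimination phase on AAF; a single phase suffices for
  everyone, and a child still symptomatic on AAF can be ruled out without
  a second elimination period.

Outcomes are total formula cost (USD, healthcare-provider perspective,
direct formula costs only) and total symptom-free months across the
cohort. No discounting is applied (the horizon is 24 months of age), no
QALY weighting, and no indirect, out-of-pocket or comorbidity costs.

## Cohort derivation

```{r}
cohort_breakdown(cmpa_parameters())
```

From the annual national under-6-month population (312,721; the source
table also prints 3,12,720 for this quantity — the value actually used in
the published cohort arithmetic, 312,721, is adopted), exclusively
breastfed children (42%) are excluded, since their elimination diet is
maternal rather than formula-based. Mixed-fed children (46%) stay in the
cohort and are costed as fully formula-fed by default; the
`mixed_formula_share` parameter (default 1.0) scales their formula bill if
a partial share is preferred. Of the eligible 181,379, 6.8% show
CMPA-compatible symptoms, giving the suspected cohort of 12,334. The
population incidence of confirmed CMPA is 2%, so the conditional
probability of confirmation at the challenge test is 0.02/0.068 ≈ 0.294 —
the only reading under which the published effect delta is reproducible.
Whether the source derived confirmed cases as suspected × ratio or
eligible × 2% is indistinguishable (the two are algebraically identical
here).

Rounding conventions are fixed by the published counts: the breastfed
count truncates toward zero (131,342 from 131,342.82), the suspected count
rounds half-up (12,334 from 12,333.77). Downstream, child counts flow as
continuous expectations; integers appear only in reports.

## Tree structure and accrual conventions

Each suspected child traverses a chance tree (`build_arm()`), with
incremental (cost, effect) payoffs attached to branches and accumulated
along paths; expected values come from standard rollback
(`tree_rollback()`), verified in the test suite against an independent
exhaustive path-enumeration oracle (`tree_paths()`).

* **Entry age: 3 months** (`entry_age_months`). The cohort is only
  described as "under 6 months"; 3 months is the mid-interval choice, and
  it calibrates well: with tolerance exits as below, a confirmed child
  accrues 17.28 − 3 = 14.28 symptom-free months in the AAF-first arm,
  against 51,941/3,627.6 = 14.32 implied by the published per-arm totals.
  The value is configurable.
* **Diagnostic phase: 4 weeks**, converted at `days_per_month` = 365.25/12,
  i.e. 0.9199 months. This convention, not a 1.0-month reading, reproduces
  the published 334-month headline (362.8 × 0.92 ≈ 334, where 1.0 would
  give 363).
* **Challenge schedule**: challenge tests run every 6 months from 12 to 24
  months of age. Cumulative tolerance is 56% at 12 and 77% at 24 months;
  no 18-month figure exists, so the 18-month challenge carries zero
  incremental tolerance (the conditional exit probability at 24 months is
  (0.77 − 0.56)/(1 − 0.56) ≈ 0.477). Supplying an 18-month entry in
  `tolerance_cumulative` reallocates the hazard.
* **Tolerance exit semantics** (`tolerance_exit`): by default a child who
  passes a tolerance challenge exits the model — formula cost *and*
  symptom-free accrual stop (`"stop"`). This accounting best matches the
  published per-arm month totals. The alternative `"keep_accruing"`
  continues effect (not cost) to the horizon, raising both arms' totals
  equally (every confirmed child then accrues the full 21 months in the
  AAF-first arm).
* **Maintenance mix**: after confirmation, children are maintained on eHF
  with probability 0.9 and AAF with probability 0.1 *in both arms* — under
  AAF-first, confirmed children step down to eHF, with the non-responder
  fraction returning to AAF. The step-down failure interval is taken as
  zero (immediate recognition); any other reading breaks the closed-form
  effect delta below.
* **Rescue period**: in the eHF-first arm the non-responders' extra
  diagnostic period on AAF is additive — it adds its cost on top of an
  otherwise identical maintenance timeline rather than displacing
  maintenance time — and accrues no symptom-free time (the child was
  symptomatic through the first phase; their accrual starts with
  maintenance).
* **Price bands**: monthly prices switch from the young band (AAF 1,426,
  eHF 1,170 USD) to the old band (739/673) at `age_band_switch_months` = 9,
  the age at which half the energy intake comes from complementary food —
  consistent with the consumption equations below. The published
  sensitivity table labels the bands "under/over 1 year"; the switch age is
  configurable to 12, which raises both arms' totals but leaves every
  incremental conclusion unchanged (the maintenance phase cancels between
  arms).

Symptom-free months accrue to true-CMPA children whenever they are on a
formula that controls their symptoms, the diagnostic phase included.
Challenge-negative children accrue none: their symptoms have another cause,
so the strategies cannot differ for them. The effect difference between
arms therefore has a closed form used as an independent oracle:

```{r}
closed_form_months_gained(cmpa_parameters())
```

`confirmed × (aaf_effectiveness − ehf_effectiveness) × diagnostic months`.
With the base 100% AAF effectiveness this is confirmed × 10% × 0.92 = 333.7,
reported as 334. (The package states the general two-effectiveness form so
the oracle matches the tree for any parameter set, not only the base case
where AAF effectiveness is 1.)

## The cost-accounting convention

This is the one genuinely open design area, and the package is explicit
about it. Billing each arm for the formula it actually feeds
(`cost_convention = "as_fed"`) makes the AAF-first arm *more* expensive:
all 12,334 suspected children drink the dearer formula for 0.92 months,
which outweighs the avoided rescue periods by about 2.4 million USD. Under
that accounting AAF-first is not cost-saving but buys its 334 months at a
finite ICER (≈ 7,300 USD per symptom-free month).

The published strategy totals are reproducible — each arm within 1.5%, the
cost difference within 0.4% — only under an accounting in which the two
arms' diagnostic-phase unit prices are interchanged: the cost difference
then decomposes as

```
saving = suspected × (AAF_young − eHF_young) × 0.92    (diagnostic phase)
       + confirmed × 10% × AAF_young × 0.92            (rescue periods)
       ≈ 2.90M + 0.48M ≈ 3.38M USD
```

with identical maintenance cancelling between arms. The package ships this
as `cost_convention = "published"` and uses it as the default so that the
reported tables are reproduced; the residual 0.4% gap is attributable to
unprinted internals of the original implementation. Both conventions are a
one-line config switch, all effect results are identical under either, and
the comparison table can be printed from either reference arm to keep the
dominance reading unambiguous.

```{r}
fit <- cmpa_cea()
summary(fit)
```

## Consumption equations

The monthly prices rest on standardized consumption: a 50th-percentile
male infant needs 8 kg × 78 kcal/kg/day × 30 days = 18,720 kcal at
6 months (exclusively formula-fed) and 9 kg × 77 × 30 = 20,790 kcal at
9 months (50% formula share). At 1,864 kcal per can this is 10 and
6 cans/month respectively, rounding half-up — the only simple rule
reproducing both counts (10.04 → 10 rules out ceiling, 5.58 → 6 rules out
floor). `monthly_energy()` and `cans_per_month()` expose these for audit;
the model itself consumes monthly USD prices directly, as per-can prices
are not part of the scenario.

## One-way sensitivity analysis

```{r}
cmpa_dsa()
```

`default_dsa_ranges()` reproduces the published seven ranges verbatim: the
four monthly costs at ±20%, the two tolerance probabilities at ±25% (with
the published endpoint rounding), and the suspected-cohort size at the
published 11,000/14,000 bounds (that row's published base, 12,333, is the
unrounded product rounded down rather than half-up; the ranges use the
printed value). The accompanying text says "±25% variability" while the
printed cost endpoints are arithmetically ±20%; the printed endpoints are
the verifiable artifact and are the default, with
`uniform_fraction = 0.25` available for the strict uniform reading — the
inconsistency is recorded, not resolved.

Under the published costing convention the old-band prices and the
tolerance probabilities cancel in the cost delta (maintenance is identical
across arms), so their tornado bars have zero width; the two young-band
prices dominate the tornado, consistent with the published reading that
the formula costs drive the result. Every low/high endpoint, and the joint
worst corner (AAF young at its high, eHF young at its low), leaves
AAF-first dominant — cheaper and more effective. The tornado orders by
absolute spread, so the ordering is invariant to the outcome's sign; the
output is a table (CSV via `write_cmpa_report()`), not a rendered diagram.

## Synthetic scenarios

`draw_scenarios()` generates seeded random parameter sets with the
structure of the base case, the conventional health-economics choices:
probabilities from beta distributions parameterized by mean (the base
value) and concentration (default 100, roughly a ±5-point spread on a 0.9
probability); costs from gamma distributions parameterized by mean and
coefficient of variation (default 0.2). Structural constraints hold by
construction: confirmed incidence is suspected × a beta confirmation
ratio, the tolerance pair is sorted post-draw (a documented small bias
toward wider pairs, accepted for a test utility), breastfeeding fractions
are redrawn if their sum exceeds 1, and AAF effectiveness stays at base (a
beta with mean 1 is degenerate). Draws restore the caller's RNG state.

What the generator emulates is the *parameter* uncertainty of a scenario —
it does not emulate individual-child heterogeneity, correlated price
movements, or time-varying tolerance hazards; passing fuzz tests therefore
demonstrates robustness of the arithmetic across plausible scenario
configurations, not validity for any particular real population.

## Numerical choices and degenerate inputs

* Chance-node probabilities must sum to 1 within 1e-9; violations name the
  node. Trees are validated before every rollback and enumeration.
* The tree-vs-closed-form effect equivalence is asserted at 1e-6 months.
* `round_half_up()` (ties away from zero) is used for reported children
  and cans; R's banker's rounding would give 12,333 children.
* A zero-length diagnostic phase, perfect eHF effectiveness, equal prices
  with equal effectiveness, zero tolerance, and an all-confirmed cohort
  are all legal inputs and are covered by limit tests (months gained 0,
  rescue branch probability 0, fully symmetric arms, maximal cost).
* A zero suspected incidence with positive confirmed incidence is an
  error (the confirmation ratio is undefined).

## Problem sizes in the test suite

The suite runs the full 12,334-child cohort everywhere (the model is
deterministic and closed-form cheap): 1,000 random trees for the
rollback-vs-enumeration property, 10,000 scenario draws for the
distribution-mean checks, and 500 evaluated draws for the frozen
Monte-Carlo regression (94.2% of draws keep AAF-first dominant at cost
CV 0.1). These sizes are the package's own choices for stable statistics.

## Limitations

* The absolute published per-arm totals are not uniquely reconstructible
  from the printed inputs; the package reproduces them to within 1.5%
  under documented conventions and checks the incremental results tightly,
  the totals loosely.
* The cost-convention ambiguity above is inherent to the source; the
  package makes it explicit rather than hiding it.
* Single annual cohort, deterministic expectations only — no
  microsimulation, no Markov cycles, no half-cycle correction, no
  IgE/non-IgE stratification of tolerance timing.
* Direct formula costs only; indirect, out-of-pocket and comorbidity
  costs are out of scope, as is any currency conversion beyond treating
  prices as plain USD.
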