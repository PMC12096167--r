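# cmpacea

Decision-analytic cost-effectiveness model for the diagnosis and treatment
of suspected cow's-milk protein allergy (CMPA) in infants, comparing two
strategies for the elimination-diet work-up:

- **eHF-first** (standard of care): a 4-week elimination phase on an
  extensively hydrolyzed formula, followed by a challenge test; the ~10% of
  true-CMPA children whose symptoms persist on eHF receive an additional
  diagnostic period on an amino-acid-based formula before confirmation.
- **AAF-first**: the elimination phase uses an amino-acid-based formula,
  which controls symptoms in essentially all CMPA patients, so diagnosis
  completes in a single 4-week phase for everyone.

The package is written for health-economics and pediatric-nutrition
researchers who want an auditable, fully parameterized re-implementation of
this comparison: a deterministic cohort decision tree followed from model
entry to 24 months of age, accumulating formula costs (USD) and
symptom-free months, with incremental cost-effectiveness (ICER) and
dominance classification, one-way sensitivity analysis with tornado
ordering, and a seeded scenario generator for probabilistic exploration.

## The model in brief

An annual national cohort of children under 6 months (N = 312,721;
Argentina, 2019) is filtered to the formula-fed: exclusive breastfeeding
(42%) excludes a child, leaving 181,379, of whom 6.8% have CMPA-compatible
symptoms — a suspected cohort of 12,334. Confirmed CMPA has incidence 2%,
so the probability that a suspected child is confirmed at the challenge
test is 0.02/0.068 ≈ 0.294.

Each suspected child traverses a chance tree: diagnostic phase (4 weeks =
0.92 months at 30.4375 days/month) on the arm's formula → challenge test →
exit if negative; if confirmed, maintenance on eHF (90%) or AAF (10%) with
cumulative cow's-milk tolerance 56% at 12 months and 77% at 24 months
applied at the scheduled challenge tests, and age-banded monthly prices
(AAF 1,426/739 USD, eHF 1,170/673 USD below/above 9 months). Expected
payoffs are computed by standard expected-value rollback, cross-checked
against an independent path-enumeration oracle.

The effect difference between the arms has a closed form: only the eHF
non-responders gain, spending the diagnostic phase symptom-free under
AAF-first instead of symptomatic,

```
months gained = confirmed × (1 − eHF effectiveness) × diagnostic months
              = 3,627.6 × 0.10 × 0.92 ≈ 334
```

The cost accounting ships with two documented conventions
(`cost_convention = "published"` or `"as_fed"`); see the methods vignette
(`vignettes/cmpa-cost-effectiveness.Rmd`) for why they differ and what each
implies.

## Worked example

```r
library(cmpacea)

fit <- cmpa_cea()          # base-case parameters
fit
#> CMPA diagnostic-strategy cost-effectiveness analysis
#>   suspected cohort: 12,334 children, horizon 24 months
#>
#>  Formula   Cost USD Avoided cost Months without symptoms Months gained      ICER
#>      AAF 55,721,629            0                  51,803             0
#>      eHF 59,102,149    3,380,520                  51,469          -334 dominated
```

Read across the eHF row: relative to AAF-first, the standard of care costs
3,380,520 USD more over the cohort-year and loses 334 symptom-free months,
so eHF-first is *dominated* — AAF-first is cheaper and more effective.
`summary(fit)` adds the cohort breakdown and the closed-form cross-check
(333.7 months, matching the tree); `coef(fit)` returns the headline numbers
as a vector.

One-way sensitivity (the published seven ranges, tornado order):

```r
cmpa_dsa()
#> One-way sensitivity analysis (outcome: delta_cost; tornado order)
#>  ...  label_low label_high
#>  ...  dominated  dominated   (all seven rows, both endpoints)
```

Every endpoint — costs ±20%, tolerance ±25%, cohort size 11,000–14,000 —
leaves eHF-first dominated; the two young-infant formula prices drive the
widest bars. Scenario exploration:

```r
sim <- simulate(fit, nsim = 500, seed = 7, cv = 0.1)
mean(sim$aaf_dominant)
#> [1] 0.942
```

Parameters are plain YAML; the shipped base case is at
`system.file("extdata", "base_case.yaml", package = "cmpacea")` and any
scenario round-trips through `read_cmpa_parameters()` /
`write_cmpa_parameters()`.

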