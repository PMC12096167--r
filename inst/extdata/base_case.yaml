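# Base-case scenario: Argentine 2019 birth cohort, 2024 USD prices.
demographics:
  population_under_6mo: 312721
  ebf_fraction: 0.42
  mixed_fraction: 0.46
  suspected_incidence: 0.068
  confirmed_incidence: 0.02
  mixed_formula_share: 1.0
clinical:
  ehf_effectiveness: 0.9
  aaf_effectiveness: 1.0
  tolerance_cumulative:
    "12": 0.56
    "24": 0.77
  diagnostic_duration_weeks: 4
  challenge_interval_months: 6
costs:
  aaf_young: 1426
  aaf_old: 739
  ehf_young: 1170
  ehf_old: 673
  age_band_switch_months: 9
time:
  entry_age_months: 3
  horizon_age_months: 24
  days_per_month: 30.4375
conventions:
  tolerance_exit: stop
  cost_convention: published
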