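Package: cmpacea
Title: Decision-Tree Cost-Effectiveness Model for Cow's-Milk-Protein-Allergy
    Formula Strategies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic cohort decision-tree model comparing two diagnostic
    and treatment strategies for suspected cow's-milk protein allergy (CMPA)
    in infants: the standard of care starting with an extensively hydrolyzed
    formula (eHF) versus a strategy starting with an amino-acid-based formula
    (AAF). Implements cohort derivation from national demographic inputs,
    monthly formula-consumption equations, expected-value rollback of the
    strategy trees with a path-enumeration oracle, accumulation of costs (USD)
    and symptom-free months to 24 months of age, incremental
    cost-effectiveness (ICER) and dominance classification, one-way
    deterministic sensitivity analysis with tornado ordering, and a seeded
    synthetic scenario generator for probabilistic exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
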