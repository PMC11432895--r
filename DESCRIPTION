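Package: bimast
Title: Fibrosis Screening Score Derivation and Cost-Utility Modelling for Diabetic Primary Care
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates primary-care diabetic cohorts with calibrated liver-fibrosis
    structure, derives and validates a BMI+AST screening score (BIMAST) alongside
    FIB-4, NAFLD fibrosis score, ELF and transient elastography comparators, and
    evaluates screening strategies with a decision-tree plus Markov cohort
    cost-utility model including one-way and probabilistic sensitivity analysis
    and cost-effectiveness acceptability curves.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
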