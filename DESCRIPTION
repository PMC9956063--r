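Package: qsofascreen
Title: Evaluate Prehospital and Emergency Department qSOFA for Sepsis Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds suspected-infection emergency department (ED) cohorts,
    computes the quick Sequential Organ Failure Assessment (qSOFA) score in
    the prehospital and ED settings together with their sum (the combined
    qSOFA), imputes missing vital signs by iterated random-forest
    imputation, labels sepsis, septic shock and in-hospital mortality with a
    rule-based clinical surveillance definition, and evaluates and compares
    the scores' discrimination: c-statistics with DeLong variance, paired
    DeLong tests, per-cutoff sensitivity, specificity, and predictive
    values with confidence intervals, score-transition tables, and the
    added-capture statistic.  A synthetic cohort generator with calibrated
    defaults makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    ranger,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
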