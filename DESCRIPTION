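Package: noctiguard
Title: Prediction and In-Silico Mitigation of Nocturnal Hypoglycemia in
    Type 1 Diabetes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study nocturnal hypoglycemia (NH) in people with type 1
    diabetes under multiple daily injection therapy. Provides a virtual-cohort
    generator (a minimal lumped glucose-insulin model with an overnight
    insulin-sensitivity modification calibrated to a target NH prevalence),
    continuous glucose monitoring (CGM) preprocessing with gap interpolation
    and night labeling, engineering of 17 time-domain features including
    bolus/carbohydrate/activity on-board models and the Kovatchev blood
    glucose risk indices, population (leave-one-patient-out) and personalized
    support vector machine classifiers tuned by nested stratified fivefold
    cross-validation, confusion-matrix and ROC performance metrics, and an
    in-silico rescue-carbohydrate intervention study with time-in-range
    outcomes and exact Wilcoxon signed-rank statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    e1071
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite
Config/testthat/edition: 3
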