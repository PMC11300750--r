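Package: radloo
Title: Radiomic Feature Stability, Nested Leave-One-Out Evaluation, and
    Adaptive Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating tabular radiomic features on medium-sized
    cohorts: a perturbation-based instability score computed over a grid of
    segmentation-mask variants and gray-level bin widths, correlation-based
    redundancy correction with a principal-component sanity check, a nested
    leave-one-out cross-validation engine with per-fold hyperparameter grid
    search and classification-threshold calibration, distributional
    (per-fold) feature importance for random forests, polynomial support
    vector machines and logistic models, and a greedy adaptive feature
    selection procedure seeded by exact one-dimensional 2-means clustering
    of importances. Includes a synthetic cohort generator with planted
    informative, redundant and perturbation-sensitive features so that every
    stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    e1071,
    jsonlite,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
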