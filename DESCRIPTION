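Package: vdseverity
Title: Vitamin D Deficiency Severity Prediction from Questionnaire Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-invasive grading of vitamin D deficiency severity from
    questionnaire features. Provides a synthetic cohort simulator with
    seasonal serum structure and configurable effect sizes, a preprocessing
    chain (chained-equation imputation, IQR outlier capping, z-score
    standardization, category aggregation, mixed encoding, SMOTE-NC class
    balancing), wrapper feature selection by a binary whale optimization
    algorithm with simulated-annealing memetic refinement, an out-of-fold
    stacking classifier with a softmax meta-model, and evaluation utilities
    (confusion matrices, per-class metrics, cross-validation reports,
    masked correlation reports, seasonal normalization).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    utils,
    xgboost
Suggests:
    nnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
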