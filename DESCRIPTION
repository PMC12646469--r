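Package: ivfabc
Title: Hybrid Logistic Regression-Artificial Bee Colony Feature Selection
    for IVF Outcome Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting embryo-transfer success in in vitro
    fertilization (IVF) cohorts from binary supplement, lifestyle and
    clinical indicators. Implements an artificial bee colony (ABC)
    metaheuristic that searches feature subsets using cross-validated
    classifier performance as fitness, a leakage-safe evaluation harness
    with SMOTE oversampling confined to training folds, L1-regularised
    logistic feature selection, active-ingredient binarization of
    supplement intake records, calibration and discrimination metrics,
    paired-fold significance tests, and LIME-style local surrogate
    explanations. A synthetic cohort generator with configurable planted
    logistic outcome signal makes every stage testable without access to
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    randomForest,
    e1071,
    rpart,
    class,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
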