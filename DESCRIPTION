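Package: harf
Title: Heterogeneity Aware Random Forests for Drug Sensitivity Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Regression random forests for predicting drug sensitivity (dose-
    response AUC) across heterogeneous cancer types. Implements Heterogeneity
    Aware Random Forests (HARF), which infer a test sample's cancer category
    from the class composition of the leaf nodes it reaches and then predict
    from the category-agreeing trees only, together with a multivariate
    extension (mHARF) using a Mahalanobis node cost for joint multi-drug
    prediction. Also provides the closed-form Bayes threshold and Bayes error
    of the idealized independent-tree vote classifier, a pathway-inspired
    two-class cell-line simulator for end-to-end testing, and a
    cross-validation harness with the standard comparison experiments
    (cancer-specific versus integrated forests, top-tree selection, two-stage
    classify-then-regress baselines, one-hot encoded forests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    randomForest
Config/testthat/edition: 3
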