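Package: sarqspr
Title: Predicting the Specific Absorption Rate of Iron Oxide Nanoparticles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for quantitative structure-property modelling of
    magnetic hyperthermia performance. Harmonizes heterogeneous literature
    records of superparamagnetic iron oxide nanoparticles (unit
    canonicalization, M_xFe_(3-x)O_4 composition arithmetic, SAR
    renormalization), derives polyhedral core surface-area/volume descriptors
    for five particle morphologies with a Monte-Carlo geometry oracle,
    assembles a 30-feature predictive table, performs stratified weighted
    splitting with Yeo-Johnson target transformation, tunes twelve regression
    families by sequential model-based hyperparameter search with
    overfitting-gap trial selection, and quantifies uncertainty and feature
    impact via split-conformal prediction intervals, permutation importance,
    Spearman redundancy clustering, and Shapley attributions. A synthetic-data
    generator with a known ground-truth SAR function makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    caret,
    e1071,
    glmnet,
    jsonlite,
    mixOmics,
    nnet,
    ranger,
    rpart,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
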