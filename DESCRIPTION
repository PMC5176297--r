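Package: mirstack
Title: Meta-Prediction of pre-miRNA Hairpins by Stacking Heterogeneous
    Predictor Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Combines the heterogeneous outputs of several pre-miRNA
    classifiers (binary calls, bounded scores, heavy-tailed probability
    ratios with sentinel tokens) into a single meta-prediction. Provides
    score-table input/output with per-predictor output dialects, staged
    non-linear preprocessing (numericalization and min-max normalization;
    log-shift with sentinel values for heavy-tailed scores; principal
    component rotation), a single-hidden-layer logistic neural network
    meta-learner trained by per-sample gradient descent with test-subset
    early stopping, stratified multi-fold cross-validation with a
    train/test/validation rotation, sensitivity/specificity/accuracy/
    Matthews-correlation evaluation, pairwise true-prediction overlap and
    coverage analysis, and a seeded generator of synthetic score panels
    with tunable per-predictor accuracy and correlated errors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
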