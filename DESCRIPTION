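Package: riskfuse
Title: Tier-Stratified Multi-Modal Text Classification for Clinical Risk
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds tier-stratified suicide-risk classifiers from clinical
    note text by fusing open-vocabulary (n-gram count) and closed-vocabulary
    (lexicon) features into a joint matrix whose feature sets are balanced by
    an alpha/beta selection-probability weighting inside a gradient-boosted
    tree learner. Includes matched case-control cohort construction with
    standardized-mean-difference diagnostics, pre-index note window
    filtering, patient-grouped data partitioning and cross-validation,
    note-to-patient probability aggregation, bootstrap-interval AUC
    evaluation, and a synthetic matched-cohort corpus generator with
    plantable semantic or count signal for end-to-end validation without
    restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
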