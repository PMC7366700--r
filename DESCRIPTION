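Package: rpcascade
Title: Reciprocal-Perspective Cascaded Rescoring of Pairwise Interaction Predictions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Refines sparse pairwise interaction scores (e.g. integrative
    miRNA-gene target predictions) by cascaded rescoring. For every entity the
    package builds a One-to-All rank-order curve of its predicted scores,
    locates a local decision baseline (Kneedle knee on LOESS-smoothed dense
    curves, score median on sparse ones), extracts thirteen reciprocal
    context features per pair, and trains a second-stage gradient-boosted or
    random-forest classifier on validated positives and uniformly sampled
    negatives. Includes paired bootstrap ROC/PR evaluation with Welch tests,
    difference-of-score candidate discovery, lambda-weighted re-ranking,
    mirDIP-convention confidence tiering, and a synthetic-data generator with
    planted reciprocal structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xgboost,
    ranger,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
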