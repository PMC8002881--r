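Package: protcleave
Title: Protease Cleavage-Site Prediction and Proteolytic Susceptibility
    Scoring with Deep Bidirectional Recurrent Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protease cleavage sites in protein sequences with an
    ensemble of deep bidirectional LSTM classifiers trained on windowed
    sequence and structure encodings, with class weighting for the extreme
    site/non-site imbalance, transfer learning from group-generic models
    with frozen early layers, and early stopping on validation F1. Scores
    per-protein susceptibility to UV-, ROS- and protease-mediated
    proteolysis from amino-acid composition, disulfide content and
    high-confidence predicted cleavage sites. Includes evaluation machinery
    (MCC, F1, ROC/AUC with bootstrap confidence intervals, non-tryptic site
    extraction from peptide evidence, cleavage-density maps, group
    comparison) and a seeded rule-based synthetic data generator that gives
    every stage a ground-truth oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
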