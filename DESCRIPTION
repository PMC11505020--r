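Package: eegensembles
Title: Ensemble Classification Pipelines for Two-Class EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Five ensemble pipelines for binary (normal/abnormal) EEG epoch
    classification: equidistant parameter assessment with kappa diversity,
    k-means pruning, annealed ranking determination and divide-and-conquer
    voting driven by the ESCD (sum of connection and distance) filter;
    infinite-ICA latent features with a random-subspace SVM/hybrid ensemble;
    genetic-algorithm feature selection with bagged SVMs; Hilbert-Huang
    transform features with GA-tuned tree ensembles; and factor analysis
    feeding a layered k-nearest-neighbour classifier with IQR outlier
    rejection. Includes EDF ingestion, a rich EEG feature bank, a synthetic
    two-class EEG generator, stratified cross-validated evaluation and a
    small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    e1071,
    nnet,
    rpart,
    randomForest,
    xgboost,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    class,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
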