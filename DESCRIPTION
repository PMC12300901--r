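Package: nppred
Title: Ensemble Prediction of Neuropeptides from Sequence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classify peptides as neuropeptides (NPs) or non-neuropeptides
    from primary sequence alone. Implements an eight-family physicochemical
    descriptor engine (amino acid and pseudo amino acid composition, CTD,
    quasi-sequence-order, scale-based properties, k-mer and curated 3-mer
    motif counts, conformational propensities, and composite logistic
    features), ReliefF feature weighting with a Pearson redundancy screen, a
    k-mer skip-gram embedding feeding a small convolutional network, and a
    hard majority-vote ensemble of a radial SVM, extremely randomized trees,
    and the CNN branch. Also provides the supporting dataset algebra
    (identity-based redundancy filtering and train/test leakage screening),
    confusion-matrix and ROC evaluation with stratified cross-validation,
    class-conditional sequence-composition analytics, and a seeded synthetic
    peptide generator so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils,
    Biostrings,
    bio3d,
    e1071,
    ranger,
    rpart,
    randomForest,
    xgboost,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
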