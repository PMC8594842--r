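Package: afcf
Title: Classifier Fusion for Atrial Fibrillation Detection from RR Intervals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A meta-level ("algorithmic crowdsourcing") pipeline for atrial
    fibrillation (AFib) screening from short single-lead ECG recordings.
    Computes 24 heart-rate-variability features from RR-interval series
    (time-domain statistics, Lomb-Scargle spectral band powers, sample and
    fuzzy entropies, a Lorenz-plot AF-evidence score), ranks base AFib
    classifiers and ECG features by random-forest out-of-bag permutation
    importance, fuses the top-ranked ones with a decorrelated 500-tree
    random forest (one sampled feature per split, cross-entropy splitting,
    growth to purity), and evaluates the fused detector with standard
    diagnostic metrics, ROC/precision-recall curves, and a clinical
    screening-burden calculator. Includes seeded synthetic generators for
    RR series of named rhythms and for correlated classifier-vote ensembles
    so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
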