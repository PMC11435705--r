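Package: emgadapt
Title: Active-Learning Relation Networks for Cross-Subject Surface EMG
    Activity Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an active-learning framework for adapting surface
    electromyography (sEMG) activity classifiers to unseen subjects. A twin
    relation network scores each sliding window against per-class template
    windows; two auxiliary classifier heads trained with a discrepancy
    objective define a data-importance statistic that partitions unlabeled
    target windows into a fine-tuning sample set ("important" data near the
    decision boundary) and a template pool ("confident" data near the domain
    centre). Adaptation is bidirectional: backward gradient updates on the
    sampled windows and forward re-selection of class templates by PCA plus
    K-means medoids. Includes signal preprocessing (Butterworth filtering,
    peak normalization, sliding-window segmentation), a seeded multi-subject
    synthetic sEMG cohort generator with a controllable cross-subject
    distribution gap, and a leave-one-subject-out experiment harness with
    template and sampling ablations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    signal,
    stats,
    tibble,
    utils
Suggests:
    MASS,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
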