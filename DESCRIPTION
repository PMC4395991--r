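Package: ssmtree
Title: Covariance-Pattern Features and Decision Trees for FDG-PET Brain
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies parkinsonian syndromes from FDG-PET brain volumes.
    Implements the scaled subprofile model (SSM/PCA): intensity masking at a
    fraction of the whole-brain maximum, log transform, double centering, and
    principal component analysis yielding Group-Invariant Subprofile (GIS)
    covariance patterns and per-subject expression scores; unseen subjects are
    projected onto a trained model. Subject scores feed a from-scratch C4.5
    decision-tree classifier with gain-ratio splitting and pessimistic
    pruning, plus a harness of comparison classifiers. Validation tools
    provide leave-one-out cross validation with per-fold feature
    re-extraction, AIC and variance-based component preselection, and
    permutation significance testing. A synthetic cohort generator embeds
    known covariance patterns in brain-like volumes so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    randomForest,
    rlang,
    rpart,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    MASS,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
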