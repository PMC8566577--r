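Package: fbcsp
Title: Filter-Bank Common Spatial Patterns for EEG Emotional Valence Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-class emotional-valence detection from low-density
    EEG. Implements a 12-band filter-bank Common Spatial Pattern (FB-CSP)
    feature-extraction pipeline alongside a-priori hemispheric-asymmetry
    features (frontal pair differences and the frontal alpha-asymmetry
    index), six classifier families evaluated under trial-grouped stratified
    k-fold cross-validation in within-subject and cross-subject modes, and a
    metrological-reference agreement analysis (polarized stimulus selection,
    Bland-Altman limits of agreement, Spearman rank correlation). A synthetic
    multichannel EEG generator with planted band-localized spatial-covariance
    effects makes every stage testable without access to recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    signal,
    MASS,
    e1071,
    randomForest,
    glmnet,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    class
Config/testthat/edition: 3
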