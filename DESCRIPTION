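Package: ictalmotion
Title: Video-Based Quantification and Classification of Motor Seizure Semiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies motor seizure semiology from bedside (near-infrared style)
    video and classifies hyperkinetic, tonic, and tonic-clonic seizures. Converts
    frame sequences into a one-dimensional motion signal via adaptive
    Gaussian-mixture background subtraction, detects clonic (rhythmic) movement by
    sparse optical-flow path tracking with a direction-reversal rule, summarises
    signals with the catch22 statistic collection in static and lag-delta
    (temporal) modes, embeds seizures in two dimensions with train-frozen PCA plus
    agglomerative clustering, and evaluates a multivariate LSTM
    fully-convolutional time-series classifier under repeated leave-one-out
    cross-validation. Includes a synthetic-video generator with ground truth for
    the three kinematic archetypes so the full pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    EBImage,
    Rcpp,
    vegan,
    cluster,
    tiff
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    mclust
Config/testthat/edition: 3
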