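Package: fusiconn
Title: Static and Dynamic Functional Connectivity Analysis for
    Functional Ultrasound Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for pharmacological functional ultrasound
    imaging (fUSI) cerebral-blood-volume time series: zero-phase Butterworth
    bandpass filtering and motion-frame censoring, ROI-pair and seed-based
    Pearson functional connectivity with Fisher-Z normalization, Monte-Carlo
    cluster-extent correction of pixel-wise statistical maps, regional
    homogeneity via Kendall's coefficient of concordance, sliding-window
    dynamic connectivity with SVD-elbow model selection and k-means brain-state
    clustering, state occupancy and Markov-entropy metrics, and a mixed
    repeated-measures ANOVA layer with sphericity handling, Tukey HSD post-hoc
    tests and Hedges g effect sizes. Ships a synthetic-session generator with
    planted covariance states and group effects so that every stage of the
    pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo:
    Rcpp
Suggests:
    car,
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
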