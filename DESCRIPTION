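Package: ayu
Title: Brain-Age Prediction from Static Functional Connectivity with
    Attention-Augmented Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes static functional-connectivity (sFC) matrices from
    parcellated resting-state fMRI time series, fits small
    attention-augmented convolutional networks (VGG5, ResNet5) that
    classify subjects into four age groups or regress chronological age,
    and attributes predictions to connectome edges via integrated
    gradients with signed node-strength and age-trajectory summaries.
    Includes a synthetic-cohort generator that plants age-dependent
    correlation trajectories (linear decline, inverted-U) so the whole
    pipeline is testable without access to imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
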