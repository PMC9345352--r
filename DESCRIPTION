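Package: segscore
Title: Two-Stage ROI Segmentation and Score Regression for 3D Brain MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A two-step pipeline for predicting a continuous score from 3D
    volumetric images: multi-class region-of-interest segmentation with an
    improved 3D U-Net (residual recombination blocks, dilated-convolution
    squeeze-and-excitation attention, bilateral symmetry label merging),
    followed by per-structure minimum-bounding-cube normalization feeding a
    volumetric CNN regressor. Includes Dice and average-surface-distance
    evaluation, a resampled evaluation harness, and a synthetic
    symmetric-phantom generator so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
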