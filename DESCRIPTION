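Package: bcgmixer
Title: Ballistocardiogram Spectrogram Imaging and ConvMixer Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting hypertension from single-channel
    ballistocardiogram (BCG) recordings: robust z-score normalization based on the
    median absolute deviation, fixed-coefficient Chebyshev type II bandpass
    filtering, non-overlapping 30-second segmentation, short-time Fourier
    spectrogram heat-map imaging, and a from-scratch ConvMixer convolutional
    classifier trained with stochastic gradient descent and evaluated under
    k-fold cross-validation. Includes a synthetic ballistocardiogram cohort
    generator so every stage can be exercised and tested without access to
    clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    signal,
    tibble,
    dplyr,
    rlang,
    readr,
    jsonlite,
    png,
    ggplot2,
    generics,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
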