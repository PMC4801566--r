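Package: caehar
Title: Continuous Autoencoders for Wearable-Sensor Activity Recognition
Version: 0.1.0
Authors@R: person("caehar", "developers", role = c("aut", "cre"),
    email = "caehar@example.org")
Description: Tools for classifying human activities from windowed
    multi-channel wearable-sensor signals. Implements a continuous
    autoencoder whose pre-activations receive additive zero-mean Gaussian
    stochastic units and whose activation is a gain- and
    steepness-parameterised zero-centred sigmoid; a per-sample stochastic
    gradient descent trainer with an early-break rule that stops once the
    monitored loss stays below a threshold for a fixed number of
    consecutive epochs; a deep belief network built from two greedily
    pretrained autoencoders plus a supervised backpropagation output
    layer with momentum and dropout; time- and frequency-domain feature
    extraction (mean, mean absolute deviation, skewness, inter-axis
    correlation, top FFT and cepstrum peaks) over 5-second 125-sample
    45-channel segments; PCA feature reduction on the channel axis;
    synthetic swiss-roll and multi-sensor activity data generators;
    stratified K-fold evaluation with confusion matrices; and a
    command-line interface over plain-text segment directories.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
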