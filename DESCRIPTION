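Package: ictalcae
Title: Supervised Convolutional Autoencoders for Seizure Detection in
    Multichannel EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint reconstruction-classification deep learning for
    ictal/interictal scalp EEG. Minimally pre-processed multichannel EEG
    segments are encoded by a convolutional autoencoder whose latent
    representation feeds either a multilayer-perceptron or a bidirectional
    LSTM classification head; the network is trained against a weighted sum
    of binary cross-entropy and mean-squared reconstruction losses and
    evaluated by stratified tenfold cross-validation. Includes a seedable
    synthetic EEG generator, a minimal EDF reader/writer with plain-text
    seizure annotations, the full segment preparation pipeline
    (balancing, per-channel z-scoring, global min-max scaling, stratified
    fold assignment), reference implementations of every layer primitive,
    and cross-validation drivers with confusion-matrix metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ggplot2,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
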