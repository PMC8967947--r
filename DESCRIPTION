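Package: zpbci
Title: Zero-Padded Spectral Features and a Convolutional Classifier for
    SSVEP/SSMVEP Brain-Computer Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Frequency recognition for steady-state visual evoked potential
    (SSVEP) and steady-state motion visual evoked potential (SSMVEP)
    brain-computer interfaces.  EEG epochs are zero-padded in the time
    domain so that the discrete Fourier transform bins coincide exactly
    with the stimulation frequencies and their harmonics, the resulting
    power spectral density values are assembled into a bins-by-channels
    feature matrix, and a small convolutional network (implemented in
    compiled code with batch normalization, leaky rectifier units and Adam
    training) classifies the feature matrices.  Includes a synthetic
    multichannel EEG generator with phase-coded sinusoidal responses,
    configurable harmonic amplitudes, subject visual latency and
    1/f-plus-white background noise; IIR band-pass preprocessing, channel
    selection and sliding-window epoching; stratified 10-fold
    cross-validation with confusion-matrix metrics; and the Wolpaw
    information transfer rate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
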