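Package: doaindex
Title: Depth-of-Anesthesia Index Estimation from Single-Channel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the depth of anesthesia from single-channel EEG
    recorded during sevoflurane anesthesia. Extracts a 46-dimensional hybrid
    feature vector per 5-second window (40 half-Hz spectral bins over
    30-50 Hz, two band-averaged spectra, permutation entropy, sample
    entropy, wavelet entropy and the alpha-ratio), converts end-tidal
    sevoflurane concentration to effect-site concentration with a
    first-order effect-compartment model, regresses effect-site
    concentration with a sparse denoising autoencoder stacked onto an LSTM
    network, and evaluates any candidate index with the prediction
    probability (Pk) concordance statistic. Includes a synthetic
    anesthesia-session simulator for end-to-end validation and
    leave-one-subject-out cross-validation tooling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
LinkingTo:
    Rcpp,
    RcppArmadillo
Config/testthat/edition: 3
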