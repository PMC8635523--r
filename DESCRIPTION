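Package: anaspec
Title: Adventitious Respiratory Sound Classification via Spectrogram
    Enhancement and Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of adventitious (abnormal) respiratory
    sounds: a parametric simulator of the seven classical adventitious
    classes (wheeze, rhonchi, stridor, squawk, fine and coarse crackle,
    pleural rub) over a vesicular-breath background; one- and two-sided
    discrete Fourier spectra and short-time Fourier spectrograms;
    Artificial Noise Addition (ANA), a coherent spectral self-addition
    that brightens faint time-frequency structure without altering
    bin-to-bin magnitude ratios; spectrogram image rendering, texture
    descriptors and feature maps; stratified dataset splitting with
    horizontal-flip augmentation; and a small convolutional-network
    training backend with an AlexNet-style layer registry, per-class
    precision/recall/F1 reports and training-history export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    signal,
    jsonlite,
    png,
    EBImage,
    ggplot2,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    caret,
    withr
Config/testthat/edition: 3
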