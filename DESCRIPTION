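Package: AuNPquant
Title: Histology-Based Quantification of Silver-Enhanced Gold Nanoparticle
    Biodistribution
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies gold-nanoparticle (AuNP) biodistribution from
    silver-enhancement-stained histological sections. Calibrated section
    images are delineated into regions of interest, tiled into overlapping
    patches, bootstrapped with weak labels from colour-channel-specific
    dynamic thresholding and morphology, segmented by a small U-Net-like
    convolutional network trained under a slide-level k-fold rotation, and
    re-concatenated without boundary effects or double counting. Individual
    deposits are identified by connected-component analysis and summarised
    as positive-pixel densities per square millimetre, percent-positive
    signal per section, and deposit-size histograms per organ. A synthetic
    histology generator with exact ground truth makes every stage testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    EBImage,
    png,
    tiff,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
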