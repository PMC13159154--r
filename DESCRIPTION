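Package: silicostain
Title: Imaging-Based Drug-Response Analysis and In Silico Staining for
    Cancer Organ Chips
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tested pipeline for imaging-based phenotypic drug-response
    analysis on microfluidic cancer organ chips. Generates synthetic paired
    bright-field and fluorescence (DAPI/TRITC) chip images with known ground
    truth; performs pre-analytical processing (tile stitching, maximum
    intensity projection, rolling-ball background subtraction, Gaussian
    smoothing); segments single cells and aggregates and computes viability
    metrics (viable area, viability percent); ranks imaging metrics by
    Z'-factor and fits four-parameter logistic dose-response curves (IC50,
    AUC); trains per-channel convolutional encoder-decoder models that
    predict fluorescence staining from bright-field images, evaluated by
    SSIM, PSNR and feature-level Pearson correlation; and derives
    longitudinal, baseline-subtracted drug-response measures from the
    predicted stains.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    igraph,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
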