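Package: hicdiffuse
Title: Denoising Diffusion Models for Single-Cell and Bulk Hi-C Contact Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Removes Gaussian noise from single-cell and bulk Hi-C chromosomal
    contact matrices with denoising diffusion probabilistic models, in both an
    unconditional (unsupervised) and a condition-on-the-observation
    (supervised) mode. Provides the forward noising process with linear and
    sigmoid variance schedules, reverse-chain samplers, two noise-predictor
    backbones (a deep residual network and a U-Net with multi-head
    self-attention) trained by minibatch gradient descent, 64x64 tiling
    inference for whole-chromosome matrices, range normalization utilities,
    a synthetic single-cell Hi-C generator with power-law distance decay and
    TAD block structure, and an evaluation suite (PSNR, SSIM, MSE, SNR, the
    HiCRep stratum-adjusted correlation, and TAD insulation-score L2
    dissimilarity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    Rcpp,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
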