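Package: redct
Title: Recursive Residual Encoder-Decoder Denoising for Low-Dose CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Low-dose CT image denoising with a weight-shared recursive
    shallow residual encoder-decoder network trained under a joint
    pixel-wise and perceptual loss, followed by a clustering-based
    water-equivalent tissue optimization. Includes a parallel-beam
    projection-domain noise simulator (radon transform, Poisson photon
    statistics, filtered back projection) for generating paired
    normal-dose/low-dose phantom data, a patch-based training loop with
    checkpointing, and PSNR/SSIM/RMSE evaluation with report aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    purrr,
    jsonlite,
    EBImage,
    png,
    tiff,
    ggplot2,
    generics,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
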