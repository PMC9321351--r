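Package: usdespeckle
Title: Speckle Suppression for Ultrasound Images via Mutual-Information
    Block Matching and Low-Rank SVD Shrinkage
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A despeckling toolkit for single-channel ultrasound-style
    images. Implements a clustered block-matching filter: texture-aware
    superpixel segmentation using local tri-directional patterns, mutual
    information patch grouping within clusters, homomorphic (log-domain)
    weighted nuclear norm shrinkage of the stacked patch tensors by
    singular value decomposition, mutual-information weighted
    re-aggregation, and a guided (Gaussian-adaptive) bilateral filter as
    an edge-enhancing post-processing stage. Ships a synthetic cyst
    phantom generator with Rayleigh and parametric multiplicative speckle
    models, and the standard despeckling quality metrics (speckle index,
    speckle suppression index, SMPI, PSNR, SSIM, edge preservation index,
    autocorrelation resolution).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
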