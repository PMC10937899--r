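Package: cryopick
Title: Transformer-Based Particle Picking for Cryo-EM Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end particle-picking pipeline for single-particle
    cryo-electron microscopy. Raw micrographs are denoised by a classical
    filter chain (Gaussian, non-local means, adaptive Wiener, CLAHE and
    guided filtering), fed to a set-prediction detector built from a
    residual convolutional backbone and a transformer encoder-decoder with
    learnable particle queries, and trained with a bipartite-matching
    (Hungarian) loss combining classification, L1 box regression and
    generalized-IoU terms. Predicted particles are filtered by a confidence
    percentile and exported as per-micrograph box files and a merged STAR
    file for downstream 2D classification and 3D reconstruction. A
    synthetic-micrograph simulator with exact ground truth, COCO/MRC/STAR
    readers and writers, and coordinate-matching evaluation metrics
    (precision, recall, F1, Dice) make the whole pipeline testable without
    external data. The neural-network core runs on a compact reverse-mode
    automatic-differentiation engine included in the package.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    tibble,
    generics,
    ggplot2,
    rlang,
    withr,
    png,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
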