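Package: usgan
Title: Semi-Supervised and Domain-Adaptive Lung Field Segmentation with a
    U-Shaped Adversarial Network
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generative-adversarial semantic segmentation for chest
    radiograph-like images in which the discriminator is a U-shaped
    encoder-decoder assigning every pixel one of three labels (lung,
    background, fake). Implements the pixel-level semi-supervised
    adversarial loss, an unsupervised domain adaptation mode that reuses
    the same loss with source images as the annotated pool and target
    images as the unannotated pool, parameter-efficient generator blocks
    built around pointwise convolutions, analytic parameter and FLOP
    accounting, Dice and Jaccard evaluation, and a synthetic phantom
    generator with exact ground-truth masks and controllable intensity
    domain shift so every training path is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    tools,
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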