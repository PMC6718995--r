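Package: dualpathnet
Title: Dual-Path Convolutional Networks for Sensor-Data Images and Fundus Photographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A declarative family of dual-path convolutional neural network
    architectures with an exact output-shape calculus, a five-zone encoder that
    turns five-parameter gas-sensor specimens into grayscale training images
    (with air-pressure range augmentation), fundus-style image preprocessing
    (shorter-edge resize, central square crop, class-distribution statistics),
    a reproducible SGD training and evaluation harness, and activation-space
    analysis (pooled-feature extraction, dead-unit census, 3-D t-SNE
    embedding). Includes synthetic-data generators so the full pipeline is
    testable offline on a single CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    png,
    yaml,
    jsonlite,
    withr,
    EBImage,
    readr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
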