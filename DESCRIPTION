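Package: ucpanel
Title: Stable Gene Panel Discovery for Ulcerative Colitis Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A reproducible pipeline for discovering a small panel of genes
    that discriminates ulcerative-colitis colon samples from controls using
    multi-study microarray expression data. Provides probe-to-gene
    collapsing, K-nearest-neighbour imputation, gene-intersection merging
    and per-sample z-scoring; a perturbation-based minimum-norm feature
    selector (DRPT) with local-maximum magnitude filtering, redundancy
    pruning and entropy ranking; stability selection across repeated runs
    scored by cross-validated average precision; QQ-based selection-frequency
    thresholding; linear support-vector-machine model building with
    precision-recall validation and Friedman model comparison; and a
    synthetic multi-study expression generator with planted class signal
    for end-to-end testing without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
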