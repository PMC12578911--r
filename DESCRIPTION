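Package: hssamnet
Title: Hyper-Scale Shifted Aggregation Networks for Polyp Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements the building blocks of hyper-scale shifted aggregation
    networks for colorectal polyp segmentation in endoscopic images: dual-branch
    max-diagonal pooling and index-guided unpooling, hyper-scale shifted
    aggregation skip connections, progressive reusing attention (partial-to-global
    channel attention and multiscale reusing spatial attention), a five-stage
    encoder-decoder assembled from these operators with ablation variants, a
    boundary-aware evaluation suite (Dice, HD95, mIoU, MAE, accuracy, precision,
    sensitivity, specificity), a seeded generator of endoscopy-like image/mask
    pairs, and configuration-driven training, evaluation and protocol harnesses.
    All layers run on the CPU through a compact Rcpp tensor backend with
    reverse-mode differentiation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    utils,
    stats
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
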