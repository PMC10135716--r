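Package: offtargetr
Title: Multitask Deep Learning and Count-Based Analysis of CRISPR/Cas9 Off-Target Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying CRISPR/Cas9 specificity from experimentally
    assayed off-target cleavage data (CIRCLE-seq-like read-count tables).
    Provides bulge-aware affine-gap alignment of guide targets against
    candidate off-target sites, position- and nucleotide-resolved mismatch and
    bulge propensity profiles (optionally weighted by normalized cleavage
    frequency), PAM motif censuses, and a multitask Siamese convolutional and
    bidirectional LSTM network that simultaneously classifies off-target
    sites and regresses the extent of cleavage activity. The fitted network
    can be interrogated with gradient attribution methods (saliency, smoothed
    saliency, integrated gradients, expected gradients) to recover per-position
    and per-nucleotide importance. A synthetic data generator with planted,
    recoverable structure supports end-to-end validation.
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
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    stringr,
    withr
Config/testthat/edition: 3
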