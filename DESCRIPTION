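Package: dardn
Title: Dual-Kernel Residual Convolutional Networks with DeepLIFT
    Attribution for Long DNA Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies long (multi-kilobase) DNA windows centered on CTCF
    binding sites as cancer-specific ("gained") versus constitutive using a
    dual-branch residual convolutional network trained on one-hot encoded
    sequence, and locates the sequence features driving each classification
    with a built-in DeepLIFT (Rescale rule) attribution engine.  Includes
    site-list and genome ingestion with reverse-complement and shift
    augmentation, a motif-insertion simulation benchmark with retained
    ground truth, sliding-window subsequence selection that prepares inputs
    for external motif-enrichment tools, position weight matrix and
    distance-distribution summaries, and end-to-end experiment drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
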