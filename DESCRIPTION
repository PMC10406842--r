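Package: edice
Title: Epigenomic Track Imputation by Factorized Self-Attention
Version: 0.1.0
Authors@R:
    person("Track", "Imputation Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Imputes missing epigenomic signal tracks (cell type x assay
    combinations) from observed tracks using a factorized self-attentive
    masked-reconstruction model. Provides random-track and tissue-wise
    masked training, a transfer-learning protocol for individual-specific
    imputation, model-free baselines (cross-cell averaging, tensor
    factorization), evaluation metrics including a simplified Poisson/BH
    peak caller, stratified MSE/Pearson, AUPRC and peakset
    precision/recall, negative-binomial replicate simulation with
    Wasserstein peak-shape distances, and a synthetic tensor generator so
    the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
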