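Package: tftl
Title: Transfer Learning for Transcription Factor Binding Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds three-state (bound/unbound/unresolved) transcription
    factor by region binding matrices from ChIP-seq peak summits, TFBS
    predictions and chromatin accessibility intervals matched by cell type;
    discovers cofactors via binding-vector cosine similarity; selects
    biologically relevant pre-training sets of transcription factors;
    pre-trains multi-task convolutional sequence models and fine-tunes
    single-task models by weight transfer at a reduced learning rate
    (with freezing and partial-transfer variants and PWM-based filter
    initialization); evaluates models by the area under the
    precision-recall curve; interprets models by converting convolutional
    filters to position weight matrices, by filter silencing, and by
    reference-based per-nucleotide attribution; and includes a PWM
    occupancy-score baseline plus a synthetic-data generator with known
    ground truth for end-to-end testing. The convolutional and recurrent
    training engine is implemented in the package with compiled kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
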