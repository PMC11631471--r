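Package: scMosaic
Title: Virtual Tissues from Bulk Expression and Single-Cell References
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs bulk RNA-seq profiles as sparse non-negative weighted
    sums of individual single-cell expression profiles ("virtual tissues").
    Each bulk sample is fitted by non-negative regression against a single-cell
    library, stabilised by bootstrap subsampling of the library. Fitted weights
    yield effective cell-type frequencies and cell-type-specific expression
    under any cell labelling, together with bounded relative-residual quality
    scores for genes and samples. Includes a pseudo-bulk simulation benchmark
    that introduces within-cell-type expression modifications and scores, via
    ROC/AUC on cell-type-specific differential expression, whether the changes
    are attributed to the correct cell compartment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0),
    pracma,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
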