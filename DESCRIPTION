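Package: cellstate
Title: Transcriptomic Cell-State Analysis with Signature Scoring and
    Single-Cell Lineage Mapping
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for bulk RNA-seq experiments that probe cell
    identity: median-of-ratios normalization and a negative-binomial Wald
    test for differential expression at fold-change and FDR thresholds,
    pre-ranked gene-set enrichment analysis with a gene-permutation null,
    rank-percentile scoring of adrenergic (ADRN) and mesenchymal (MES)
    signature gene sets, and Pearson-correlation mapping of bulk clone
    profiles onto a labeled developmental single-cell reference with
    mutual-exclusivity testing on binarized expression and hierarchical
    clustering of the correlation map. Includes negative-binomial simulators
    that emulate a knockout-clone study design and a four-population
    sympathoadrenal single-cell reference, so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
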