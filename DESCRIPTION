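Package: flcpipe
Title: Integrated Multiome, ChIP-seq and Bulk RNA-seq Analysis of Fetal
    Leydig Cell Differentiation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for the cross-modal computations used to
    study the differentiation of steroidogenic progenitor cells into fetal
    Leydig cells in the embryonic mouse testis: per-cell RNA and ATAC
    quality gating, cluster-level chromatin similarity over the most
    variable accessibility peaks, differential expression and differential
    accessibility testing with a fragment-depth covariate, ChIP-seq peak
    resizing, blacklist filtering and genomic-context classification
    relative to the nearest TSS, ChIP-target assignment and overlap
    statistics with differentially accessible peaks, peak-gene linkage by
    accessibility-expression correlation, hypergeometric motif enrichment
    with GC-matched backgrounds and combined transcription-factor ranking,
    and the projection of bulk-derived differentially expressed gene lists
    onto single-nucleus clusters via z-scored per-cluster averages. A
    synthetic-data module generates a self-consistent desk-scale multiome
    with recorded ground truth for every downstream recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.3)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    Biostrings,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
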