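Package: scitopic
Title: Topic-Model Discovery of Cell Types from Single-Cell ATAC-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cell-type discovery from single-cell combinatorial-indexing
    ATAC-seq (sci-ATAC-seq) data via latent Dirichlet allocation over a
    binary cells-by-peaks matrix. Provides fragment-to-cut-site
    preprocessing with barcode correction, a change-point filter for the
    binary matrix, a collapsed Gibbs sampler for LDA with a partitioned
    (distributed-style) training mode, cross-validated topic-number
    selection scored by Chib-style held-out perplexity, topic-based cell
    clustering with small-cluster augmentation, pseudobulk peak calling
    with multi-summit splitting and an iterative cluster-then-call
    pipeline, interval-overlap and tissue-expression enrichment
    statistics, and synthetic-data generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    uwot,
    mclust,
    optparse
Config/testthat/edition: 3
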