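Package: scATACkit
Title: Desk-Scale Single-Cell ATAC-Seq Fragment Processing, Peak and Cell
    Calling, Clustering and Motif Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained analysis chain for single-cell ATAC-seq
    fragment files: droplet barcode error correction against a whitelist,
    fragment deduplication and quality-control profiles (fragment-length
    histogram, TSS enrichment), open-chromatin peak calling with a
    zero-inflated three-component count mixture, cell calling with a
    two-component negative-binomial mixture, latent semantic analysis
    (IDF + truncated SVD) embedding with k-medoids and graph clustering,
    nearest-TSS peak annotation with hypergeometric term enrichment,
    PWM motif scanning at an exact p-value threshold with GC-matched
    backgrounds and robust per-cell motif z-scores, and negative-binomial
    differential accessibility. Ships a synthetic-data generator with
    planted ground truth so the whole pipeline is testable end to end.
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
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    jsonlite,
    irlba,
    igraph,
    cluster
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
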