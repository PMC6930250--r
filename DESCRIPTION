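Package: mitosr
Title: Cataloging and Profiling of Mitochondria-Derived Small RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end small-RNA-seq analysis pipeline for
    mitochondria-derived small non-coding RNAs (mitosRNAs). Raw reads are
    adapter-trimmed, size-selected to 15-27 nt, collapsed to unique
    sequences and depth-normalized by median-of-ratios size factors.
    Unique sequences are aligned with 100% identity to both strands of a
    circular mitochondrial genome, annotated by feature overlap
    (single-feature, overlapping-features, intergenic) and summarized as
    a strand-by-feature catalog. Differential expression across an
    anoxia/recovery treatment design is called with a negative-binomial
    Wald test and Benjamini-Hochberg correction. tRNA-derived fragments
    are profiled by per-base coverage, 5'/3' end classification, k-means
    expression clustering and conserved-core antisense probe design. A
    synthetic-data module simulates the full stage-by-treatment design
    with planted, anoxia-responsive tRNA fragments and a ground-truth
    table for parameter-recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
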