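Package: epireanno
Title: Epigenome-Guided Refinement of Genome Structural Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for refining a genome's structural annotation with
    histone-mark evidence. Merges multi-sample RNA-seq transcript assemblies,
    subtracts a reference annotation to nominate novel transcripts, retains
    candidates that co-occur with H3K4me3 peaks, and infers transcript strand
    from peak-center position relative to transcript ends. Also provides a
    CEAS-style partition of the genome into promoter/UTR/exon/intron/intergenic
    classes, peak-to-gene association with an upstream window, meta-gene
    profiling of coverage tracks stratified by expression quantile, a
    fold-change differential-expression rule with set-overlap summaries,
    TSS-signal clustering, and a synthetic-fixture generator with truth-based
    evaluation of the discovery pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
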