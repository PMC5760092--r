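Package: regulonscope
Title: Sigma-32 Regulon Mapping and Proteome Resource-Allocation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for defining an alternative sigma-factor regulon in
    bacteria from multi-condition transcriptomics and ChIP-seq binding
    evidence, and for quantifying the downstream proteome response.
    Implements threshold-based peak calling on binned read-density tracks
    with strand- and operon-aware promoter assignment, multi-condition
    fold-change regulon classification, TMT proteomics normalization and
    differential-abundance calls, proteomap-style mass-fraction accounting
    across a functional hierarchy, and protein half-life estimation from
    translation-shutoff chase time courses with censored reporting.  A
    synthetic-data generator plants a known regulon (direct targets,
    effect sizes, half-lives) so that every pipeline stage can be
    validated against ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
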