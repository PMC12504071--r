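Package: cnvpopdiff
Title: Read-Depth CNV Region Discovery and Copy-Number Population
    Differentiation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Windowed read-depth copy-number estimation from short-read
    data: read quality filtering, genome tiling into half-overlapping
    windows, GC-bias normalization by per-bin median scaling, CNV region
    (CNVR) calling with duplication/deletion/mixed classification, the
    Vst copy-number differentiation statistic between two populations
    with top-percentile selection, population-structure summaries (PCA,
    genomic relationship matrix, neighbor-joining tree), and offline
    hypergeometric gene-set enrichment of candidate regions.  Includes a
    two-population depth simulator with planted CNVs and a ground-truth
    channel so the whole pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
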