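Package: pachyscan
Title: Annotation and Integrative Feature Analysis of Pachytene piRNA Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: De novo annotation of pachytene piRNA clusters from mapped
    small-RNA reads using sliding-window statistics, followed by integrative
    characterization of the annotated loci: promoter CpG observed/expected
    classification, tissue-specificity scoring, control-gene-normalized
    epigenomic signal aggregation, a broad-domain extension-index statistic,
    rule-based regulatory (A-MYB, BTBD18) calls, and synteny-based
    cross-species conservation classification. Ships a synthetic-data
    generator that plants clusters with known structure so every stage of the
    pipeline can be exercised and validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
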