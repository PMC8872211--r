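Package: PlumageSV
Title: Mapping a Recessive Plumage-Colour Deletion from Short-Read Evidence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis toolkit for mapping a recessive
    plumage-colour phenotype to a non-coding structural deletion from
    short-read sequencing evidence. Provides a deterministic paired-end
    read simulator with exact coordinate-projection alignments, hard
    filtering of SNP calls, an allelic case-control association scan
    with Bonferroni thresholding, pooled read-depth log-ratio scanning,
    insert-size based structural-variant typing, soft-clip breakpoint
    resolution with junction-insertion recovery, and an in-silico PCR
    genotyping diagnostic with a Mendelian multi-locus phenotype rule
    engine, orchestrated as one reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
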