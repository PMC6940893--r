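Package: plastomics
Title: Comparative Plastome Structure, Repeats, Diversity, RNA Editing and Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated toolkit for comparative chloroplast-genome analysis
    of closely related plant accessions: quadripartite (LSC/SSC/IR) structure
    detection and region statistics, microsatellite (cpSSR) and approximate
    long-repeat censuses, sliding-window nucleotide diversity and mutational
    hotspot calling from multiple alignments, signed gene-order inversion
    detection and gene presence/absence comparison, replicate-filtered C-to-U
    RNA-editing site calling with codon-effect and physicochemical
    classification, and median-of-ratios (RLE) normalization with expression
    profile clustering. A seeded synthetic-data generator produces plastomes,
    alignments, pileups and count matrices with planted ground truth so every
    stage is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
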