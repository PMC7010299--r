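Package: retrocirc
Title: Repeat-Aware Detection of Back-Spliced Circular RNAs from Retrotransposon Consensus Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects back-spliced (circular) RNAs arising from highly repetitive
    elements such as centromeric retrotransposons, where genome-anchored circRNA
    callers fail. Implements paired-end read merging, seed-and-extend local
    alignment of merged fragments to a repeat consensus, a read taxonomy
    (LTR / nonspliced / normal-spliced / back-spliced), back-splice junction
    calling with microhomology-aware canonicalization, circular isoform
    reconstruction with in-silico divergent PCR verification, a genomic-origin
    exclusion test for candidate junctions, and RIP-versus-input enrichment,
    RPM-track and 3C-qPCR quantification. Ships a synthetic-data generator that
    emulates a CRM1-like centromeric retrotransposon so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
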