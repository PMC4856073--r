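Package: macrotene
Title: Reconstruction of Massively Amplified Yeast Chromosomes from
    Short-Read Coverage and Junction Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct the architecture of grossly expanded
    ("macrotene") yeast chromosomes carrying massive CUP1 tandem-array
    amplifications. The package models chromosomes as ordered, oriented
    segments and tandem arrays, realizes them as nucleotide sequence,
    simulates short sequencing reads with truth tracking, maps reads and
    converts depth into copies per cell, segments copy-number profiles
    into integer levels and decomposes them into amplicons, discovers
    quasi-palindromic and telomere-fusion breakpoint junctions by local
    assembly of unmapped reads, quantifies tandem-repeat copy numbers by
    two independent estimators (sequencing coverage and restriction
    fragment sizes), enumerates chromosome topologies consistent with the
    inferred constraints, and replays the three-step mechanistic model of
    macrotene chromosome formation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
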