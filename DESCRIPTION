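Package: dnecall
Title: Calling Endoribonuclease-Dependent Cleavage Sites from RNA Degradome Data
Version: 0.1.0
Authors@R: person("Degradome", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies DNE1-dependent, XRN4-sensitive 5'-monophosphate (5'P)
    cleavage sites from genotype-contrasted degradome sequencing libraries
    (PARE/GMUCT style per-position 5'-end count tracks). Implements CPM
    normalization, pseudocount log2 fold-change comparison tracks, a filter
    cascade (XRN4 sensitivity, DNE1 dependence, decapping/TSS exclusion,
    genome/transcriptome uniqueness, full-length expression check) with
    MaxSeq / Major-internal site classification, downstream site-feature
    analytics (region assignment, metagene and exon-junction profiles,
    degenerate-motif scanning, k-mer differential enrichment, set-overlap and
    half-life statistics), and a seeded synthetic-data generator with planted
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    Biostrings,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
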