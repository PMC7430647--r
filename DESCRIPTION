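Package: exofrag
Title: Classification of Extracellular tRNA Halves and Y RNA Fragments
    from Small RNA-Seq Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-alignment analysis of extracellular small RNA sequencing
    libraries. Classifies reads into 5' and 3' tRNA halves using
    transcript-coordinate windows, calls nontemplated CCA/CC/C tail status
    at tRNA 3' ends (including genome-templated tails), applies a strict
    read-qualification cascade (indel/intron filtering, 3' adapter
    requirement, end-to-end length matching, pre-tRNA exclusion), assigns
    reads to Y RNA genes, pseudogenes and repeat-derived copies with a
    fallback hierarchy, and summarizes datasets (half fractions, 5'/3'
    splits, per-family tables, 5'/3' imbalance statistics). Includes a
    synthetic-data generator that emulates extracellular RNase cleavage of
    mature tRNAs and Y RNAs together with library-preparation end-chemistry
    biases, emitting alignments, raw reads and a ground-truth table so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
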