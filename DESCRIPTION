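Package: retroforge
Title: Retrocopy and Chimerical Retrogene Discovery, Classification and
    Molecular Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a whole-genome retrocopy discovery
    workflow for annotated genomes. Detects intron-lost gene copies by
    translated homology search and spliced protein-to-genome alignment,
    classifies them as intact retrogenes or processed pseudogenes (frameshift
    or premature stop codon), identifies chimerical retrogenes that recruit
    flanking coding sequence or UTRs, attaches EST/mRNA transcription
    evidence under strict placement-disambiguation rules, and estimates
    retrocopy ages and origination rates from Li-Pamilo-Bianchi (LPB) Ka/Ks
    with a synonymous-rate calibration from ortholog pairs. A synthetic
    genome simulator with planted ground truth makes every stage testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    dplyr,
    tibble,
    rlang,
    withr,
    ggplot2,
    generics,
    stats,
    utils,
    methods,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    jsonlite,
    optparse
Config/testthat/edition: 3
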