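Package: dtxmir
Title: Small RNA Sequencing Analysis of Destruxin A-Responsive miRNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, fully synthetic-data-testable re-implementation of
    a small RNA sequencing workflow for identifying mycotoxin-responsive
    microRNAs in an insect host: read cleaning and adapter trimming, tag
    collapsing, exact genome mapping, priority-rule annotation, known-miRNA
    quantification, novel-miRNA discovery by hairpin folding with a
    dinucleotide-shuffle randomization test, the Audic-Claverie exact test for
    between-library differential expression with Bonferroni correction,
    three-predictor miRNA target-site consensus, hypergeometric term
    enrichment, and 2^-ddCt qPCR relative quantification. A simulation module
    generates all inputs with a machine-readable ground-truth ledger so every
    stage can be validated against planted truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    Rcpp,
    methods,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
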