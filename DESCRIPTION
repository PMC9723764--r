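Package: glycanseq
Title: Barcode Counting and Compositional Analysis for Lectin-Based
    Glycan Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational readout for Glycan-seq experiments, in which
    DNA-barcoded lectins report cell-surface glycan abundance through
    sequencing. Implements mismatch-tolerant barcode counting from FASTQ
    reads with separate flanking- and middle-region mismatch allowances,
    compositional normalization to per-lectin percentage profiles,
    hierarchical clustering of sample profiles, an ANCOM-style log-ratio
    differential test with Holm-Bonferroni correction, and a
    synthetic-read simulator with per-read ground truth for validating
    every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
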