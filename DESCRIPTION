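Package: ampliclone
Title: Genotyping CRISPR-Edited Clones from Barcoded Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Ampliclone", "Developers", email = "ampliclone@example.org",
           role = c("aut", "cre"))
Description: Simulates diploid CRISPR-edited cell clones and their inline-barcoded
    amplicon sequencing reads, then recovers the editing outcomes: demultiplexing
    by inline barcode, semi-global affine-gap alignment of reads against the
    wild-type and HDR-edited reference, per-read classification into WT, HDR and
    NHEJ outcomes with quality-filtered variant signatures, clone-level zygosity
    calling (mono-/bi-allelic HDR, NHEJ variants, multi-allelic clones), and the
    workflow statistics of nanofluidic single-cell chip runs: on-chip clonal
    expansion efficiency, pen cross-contamination, doubling time, export
    efficiency, post-export viability stratified by export size, staining
    positivity, and binomial screening-size planning.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    S4Vectors,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
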