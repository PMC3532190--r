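Package: mirexport
Title: Quantification of Selective MicroRNA Export into Extracellular Vesicles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A small RNA-seq analysis pipeline for measuring which microRNAs
    are selectively exported from cells into extracellular vesicles (EVs).
    Provides adapter trimming and length filtering of raw reads, ungapped
    alignment of reads to miRNA hairpin precursors with a mismatch cap,
    assignment of reads to annotated mature arms with isomiR tabulation,
    reads-per-million-mapped (RPMM) normalization with a pseudocount rule and
    exclusion-renormalization for overexpressed miRNAs, the log2(EV/cell)
    export statistic with released/retained classification and distribution
    summaries, relative RT-qPCR quantification (2^-deltaCt), cross-dataset
    rank-concordance matrices, and a synthetic-data generator with known
    ground truth that emulates the cells/EVs x non-transfected/transfected
    study design for testing every step.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    graphics,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    pheatmap,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
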