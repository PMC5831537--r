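Package: phagehost
Title: Sequence-Based Signals for Bacteriophage Host Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes and benchmarks the genomic signals that link a
    bacteriophage to its bacterial host: canonical oligonucleotide usage
    profiles (k = 1-8, codon usage, GC content), longest exact sequence
    matches via 15-mer seeding and diagonal merging, CRISPR spacer
    detection and short-read-regime spacer alignment, nucleotide and
    translated homology summaries from a seed-and-extend aligner, and
    abundance co-occurrence across metagenomic samples. Ranks candidate
    hosts per signal with a tie-aware rule, scores predictions at six
    taxonomic ranks, builds ROC curves, and compares against a random
    assignment baseline. Includes a synthetic benchmark generator that
    plants each mechanism (prophages, shared genes, acquired spacers,
    ameliorated composition, coupled abundances) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
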