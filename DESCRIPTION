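Package: palcore
Title: Discovery and Characterization of Short Palindromic Repeats in
    Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for finding and characterizing short degenerate
    palindromic repeats (REP-like elements) in bacterial chromosomes.
    Implements mismatch-tolerant scanning of IUPAC-degenerate patterns,
    per-position conservation profiling across mismatch strata,
    overrepresentation statistics against an order-k Markov background,
    de novo discovery of enriched arm-spacer palindromes, classification
    of sites by genomic context (coding overlap; divergent, convergent or
    co-directional intergenic placement; upstream distances), replichore
    strand-asymmetry tables keyed to a replication origin, spatial
    uniformity statistics, and a synthetic-genome generator that plants
    motif sites with a known truth table for end-to-end validation.
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
    rtracklayer,
    dplyr,
    tibble,
    tidyr,
    purrr,
    stringr,
    readr,
    ggplot2,
    rlang,
    jsonlite,
    yaml,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
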