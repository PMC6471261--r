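Package: mejamir
Title: Small RNA Analysis of Methyl-Jasmonate Elicitation Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for small-RNA sequencing analysis of
    a four-timepoint methyl-jasmonate (MeJA) elicitation experiment: read
    cleaning and tag collapsing, miRNA classification against mature and
    non-coding RNA references with a hairpin screen for novel candidates,
    tags-per-million quantification, exact-test differential expression for
    count pairs, short-time-series profile clustering with permutation
    significance, rule-based plant miRNA target prediction with G:U wobble
    scoring and a duplex energy-ratio criterion, miRNA-mRNA anti-correlation
    pairing, hypergeometric pathway and term enrichment, and comparative-Ct
    qPCR validation. Ships a truth-tracked synthetic data generator so the
    whole pipeline runs and is validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    generics,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings
Config/testthat/edition: 3
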