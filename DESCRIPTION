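Package: rvburden
Title: Rare-Variant Gene Burden Testing Against Reference-Panel Pseudo-Controls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Gene-level burden testing of rare coding variants in case cohorts
    against public reference-panel allele frequencies (gnomAD-style AC/AN
    tables, CSVS-style frequency tables) used as pseudo-controls. Collapses
    qualifying variants per gene, forms allelic 2x2 tables, and computes exact
    two-sided Fisher p-values, sample and conditional-MLE odds ratios, and
    exact conditional confidence intervals by noncentral-hypergeometric tail
    inversion, with Bonferroni and Benjamini-Hochberg adjustment over the gene
    family. Includes genotype-level VCF quality control (allele balance,
    genotype quality, depth, tranche), per-individual co-occurring-variant
    detection, sliding-window missense-density constraint profiling along the
    coding sequence, position-weight-matrix scoring of donor and acceptor
    splice signals with percent-variation calls and splicing-regulatory motif
    deltas, and a seeded diploid cohort simulator with planted enrichment for
    end-to-end validation without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
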