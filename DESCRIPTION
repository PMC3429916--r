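Package: msatma
Title: Microsatellite Composition and Mutation-Rate Analysis from
    Mutation-Accumulation Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying short tandem repeats (microsatellites) and
    their spontaneous mutation dynamics in mutation-accumulation (MA) line
    experiments.  Provides canonical repeat-motif taxonomy under rotation
    and reverse-complement equivalence, a deterministic seed-and-extend
    scanner for perfect and imperfect tandem repeats in FASTA sequences
    with strict and loose screening presets, conversion of
    progenitor-versus-line allele sizes into signed repeat-unit mutation
    calls and mutation-spectrum summaries, per-locus mutation-rate
    estimation with the Poisson zero-class estimator and exact binomial
    confidence intervals, and a synthetic-data module that generates
    planted-repeat genomes and stepwise-mutation MA genotype tables with
    ground truth.  All user-facing functions take data frames and return
    tibbles so analyses compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
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
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
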