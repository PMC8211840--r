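Package: poppystr
Title: Forensic Microsatellite Marker Development and Validation for Opium Poppy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for building and validating forensic short tandem
    repeat (STR) profiling systems in opium poppy (Papaver somniferum).
    Covers genome-wide perfect-microsatellite mining and candidate marker
    selection, sequence-based allele nomenclature with flanking-variant
    descriptors and short identifier (SID) labels, allelic-ladder
    construction and bin-based genotype calling from capillary
    electrophoresis peak tables, internal validation metrics (inter-locus
    and intra-colour balance, heterozygote balance, stutter ratios,
    sensitivity and sizing precision), and variety-level population
    analysis (identity analysis, discrimination, PCA and UPGMA
    clustering). A synthetic-data module simulates genomes with planted
    repeats, inbred multi-variety genotype sets and CE peak tables with
    stutter, imbalance, dropout and sizing noise so that every stage runs
    and is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    digest,
    withr,
    readr,
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
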