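Package: panmet
Title: Pan and Multi-Strain Genome-Scale Metabolic Model Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds pan genome-scale metabolic models (pan-GSMMs) from strain
    proteomes and a reaction universe, optionally expands a curated reference
    model with new content from the reference-free reconstruction, derives
    gap-filled strain-specific models, predicts strain-level metabolic
    phenotypes by flux balance analysis, and clusters strains into a
    phylometabolic tree. Includes protein clustering with a presence/absence
    matrix (PAM), three-scenario gene recovery from assemblies,
    gene-protein-reaction (GPR) boolean algebra, mass/charge balance checking,
    penalty-weighted exact gap-filling, SBML Level 3 FBC and JSON model I/O,
    binary feature tables, Jaccard/Ward strain clustering, and a seeded
    synthetic-world generator for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    BiocGenerics,
    Biostrings,
    dplyr,
    GenomicRanges,
    methods,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
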