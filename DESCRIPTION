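Package: immunopep
Title: Design of Peptide Immunogens for Antibody Production
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores every candidate immunizing peptide of a target protein
    for predicted immunogenicity (a hydrophilicity by turn-propensity product
    with a terminal-tail bonus), proteome uniqueness and cross-species
    conservation via exact epitope-length k-mer matching, and overlap with
    post-translational modification sites, sequence variants and membrane
    topology, then emits a ranked, track-aligned design report as TSV or
    JSON. Reads FASTA and a subset of the UniProt flat-text record format,
    ships the Kyte-Doolittle hydropathy and Chou-Fasman conformational
    scales, and includes a deterministic synthetic-protein generator so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
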