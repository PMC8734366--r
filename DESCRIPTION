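Package: umirep
Title: Processing and Quality Control of Barcoded, UMI-Tagged Immune Repertoire Sequencing Data
Version: 0.1.0
Authors@R: person("Repertoire", "Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for T-cell and immunoglobulin repertoire
    sequencing runs that carry inline sample barcodes and unique molecular
    identifiers (UMIs). Covers demultiplexing by barcode pattern, UMI
    consensus assembly with read-flow accounting, classification of
    undetermined reads, disambiguation of FACS-sorted cell subsets by
    frequency fold change, UMI-based cross-sample contamination detection,
    and repertoire statistics: CDR3 length spectra, clonality, diversity
    indices and rarefaction curves with saturating curve fits, pairwise
    clonotype overlap, V-J gene segment pairing usage, and hierarchical
    sample similarity clustering. Includes a seeded synthetic-data
    generator with truth labels for every stage, machine-learning feature
    export, and a single-config pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
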