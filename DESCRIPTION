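Package: cladeforge
Title: Subgroup Delineation and Gene-Content Evolution for MAG Phylogenomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for delineating subgroups on phylogenomic trees of
    metagenome-assembled genomes (MAGs) using relative evolutionary
    divergence (RED) and ultrametric stem-length criteria with dual node
    supports (ultrafast bootstrap and SH-aLRT); marker-based genome
    completeness and contamination estimation; per-subgroup gene-family
    occurrence profiling; frequency-thresholded summarisation of
    duplication, transfer, loss and origination events from gene-tree /
    species-tree reconciliations; and classification of [FeFe]-hydrogenase
    operons with motif-conservation profiling. Includes seeded synthetic-data
    generators for every input so each stage can be validated against a
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phangorn,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
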