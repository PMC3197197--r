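Package: presynet
Title: Quantitative Proteomics Seed Selection and Protein Interaction
    Network Cluster Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Turns differential stable-isotope-labeled LC-MS feature tables
    into per-protein treatment/control ratios, selects a regulated "seed
    list", expands the seeds over a literature-filtered protein-protein
    interaction background through at most two intermediates, scores
    connecting intermediates with a pooled two-proportion z-test, tests the
    subnetwork's clustering coefficient against degree-preserving shuffled
    nulls, and extracts overlapping k-clique percolation clusters. Includes
    a seeded synthetic-data module that emulates both the peptide-level
    feature tables and a provenance-annotated interaction background, so
    every stage can be validated against planted ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
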