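Package: ppinet
Title: Build, Score and Filter Context-Specific Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Consolidates experimentally validated protein-protein
    interactions from PSI-MITAB files into a non-redundant undirected
    interactome, weights each interaction with a Gene-Ontology-anchored
    Bayesian detection-method scoring scheme, filters the network by
    molecular expression and GO-annotation context, and reports standard
    network statistics (components, clustering, degree and weight
    distributions). Includes a seeded synthetic-data generator that emits
    the same file formats the pipeline reads, so the full workflow is
    testable offline. All user-facing functions take and return tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
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
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
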