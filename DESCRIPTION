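Package: sparselap
Title: Sparsity-Promoting Feedback Control of Networks with Laplacian Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to study how network topology shapes the cost of feedback
    control under Laplacian dynamics. Generates undirected network ensembles
    spanning random, modular, and centralized topologies by heat-kernel
    adaptive rewiring; designs sparsity-promoting H2 optimal state-feedback
    controllers via ADMM with a cardinality penalty and structured polishing;
    computes degree statistics, Newman-Girvan modularity with null-model
    normalization, and minimum driver-node counts from the PBH test; and
    orchestrates tau-by-gamma sweeps with tidy results tables, rank
    correlations, and regime-ordering summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
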