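Package: metnets
Title: Bipartite Metabolic Networks for Metabolomic Interpretation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Curates genome-scale metabolic models and defines directional
    bipartite metabolite-reaction networks with or without subcellular
    compartmentalization and with configurable exclusion of metabolite hubs.
    Computes single-mode bipartite graph metrics (density, degree and
    betweenness centralization, mean shortest path length, pairwise cluster
    coefficients, the small-world sigma coefficient against matched random
    bipartite ensembles, and degree assortativity of unipartite projections),
    processes metabolomic measurement tables into per-metabolite group
    comparisons (normalization, log2 fold changes, Student t-tests), and
    detects connected network clusters enriched in small p-values.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    xml2,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
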