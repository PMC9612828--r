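Package: drivermod
Title: Driver Gene and Driver Module Discovery from Somatic Mutation
    Co-Occurrence Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-step discovery of candidate cancer driver genes and driver
    modules from somatic mutation catalogs. Step one builds a weighted
    mutation co-occurrence network over the mutated genes of a case
    collection, computes six topological node features (strength, closeness,
    betweenness, a weighted PageRank variant, eigenvector centrality and a
    network-entropy perturbation score), and ranks genes with an
    unsupervised Laplacian-score feature weighting. Step two places the
    top-ranked genes on a biological graph built from protein-protein
    interactions and shared biological-process annotations and extracts
    dense, high-scoring modules with a simulated-annealing seed-expansion
    heuristic. The package also provides benchmark agreement metrics
    (precision, recall, F-measure), an empirical random-subset significance
    test for modules, hypergeometric gene-set enrichment, per-cancer
    co-mutation counts, and a synthetic catalog generator with planted
    driver structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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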