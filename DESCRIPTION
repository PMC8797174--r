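Package: poachnet
Title: Simulated Poaching Experiments on Multi-Tier Elephant Social Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how selective harvest ("poaching") perturbs the
    social networks of African savanna elephants and other species with nested
    fission-fusion societies. The package assembles population-wide weighted
    association networks from dyadic and group-level sighting counts, simulates
    network formation in virtual multi-tier populations with an individual-based
    model driven by triangular association-probability distributions, runs
    targeted (age- or betweenness-ranked) and random incremental node-deletion
    experiments with optional weak-link filtering, computes four global network
    indices (unweighted clustering coefficient and weighted diameter, global
    efficiency and leading-eigenvector modularity, all with inverse-weight link
    lengths), and summarizes targeted-versus-random contrasts with Hedges' g
    effect sizes and confidence intervals.
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
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
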