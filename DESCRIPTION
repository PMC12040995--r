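Package: ectonet
Title: Individual-Based Host-Ectoparasite Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and analyses individual-based bipartite networks between
    host individuals and ectoparasite species (fleas and gamasid mites on
    small mammals). Computes per-host position indices (individual strength,
    normalized nested rank, the specialization index d', eigenvector
    centrality on the unipartite projection), network-level structure (NODF
    nestedness and H2' specialization, standardized against the Vazquez
    constrained null model), weighted bipartite module detection with
    Guimera-Amaral within-module degree z and participation coefficient c
    role classification, within-network female-male comparisons
    (negative-binomial and Poisson infestation models, distance-based MANOVA
    and univariate permutation ANOVAs), and across-network comparative
    models (beta GLMMs on role proportions and phylogenetic GLS with
    all-subsets AIC selection). A seeded synthetic-data generator emulates
    multi-species, multi-region host-parasite surveys so the whole pipeline
    is testable without field data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    ape,
    glmmTMB,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    mclust,
    nlme,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
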