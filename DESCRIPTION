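Package: phenonet
Title: Within-Season Temporal Dynamics of Plant-Flower Visitor Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the within-season temporal dynamics of
    quantitative plant-flower visitor interaction networks. Builds daily and
    windowed sub-networks from dated visitation records, partitions temporal
    beta diversity of species and interactions into replacement and richness
    components (multiple-site Jaccard), computes pairwise Whittaker network
    dissimilarity (species, whole-network and shared-species interactions),
    relates dissimilarity to time lag and flowering overlap, detects modules
    in weighted bipartite networks by maximising Barber-type quantitative
    modularity with marginal-preserving null-model significance testing, and
    characterises module phenology with Monte-Carlo chi-squared tests and
    multinomial logistic regression of module membership on activity start
    date. Includes a flowering-season simulator with known temporal guilds
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    lubridate,
    ggplot2,
    rlang,
    stats,
    utils,
    nnet,
    vegan,
    mclust,
    withr,
    generics,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
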