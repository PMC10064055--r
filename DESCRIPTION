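Package: phyllonet
Title: Community and Bipartite Network Analysis of Paired Phyllosphere
    Fungal Assemblages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical toolkit for paired epiphytic and endophytic
    phyllosphere fungal communities sampled across a host-plant phylogeny.
    Covers OTU-table preprocessing (low-count filtering, rarefaction,
    compartment partitioning), community dissimilarity and ordination tests
    (Hellinger transform, Bray-Curtis, NMDS, ANOSIM, one-tailed Mantel,
    paired t-test on log richness), phylogenetic-signal statistics
    (Blomberg's K with permutation p, Pagel's lambda by maximum
    likelihood), weighted bipartite network metrics (H2' specialization,
    weighted connectance, WNODF nestedness, Barber modularity) standardized
    against marginal- and connectance-preserving swap-web null models, and
    secondary-extinction robustness curves fitted with y = 1 - x^a. A
    synthetic-data module generates host trees, paired OTU tables with
    controllable phylogenetic signal, and interaction matrices with tunable
    structure so the whole pathway is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    vegan
Suggests:
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
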