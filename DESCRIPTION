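Package: evoregions
Title: Evolutionary Regionalization of Tree Assemblages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to delimit and interpret the evolutionary regions of
    tree assemblages from a dated genus-level phylogeny and site-by-genus
    presence/absence data. Computes phylogenetic beta diversity (the
    one-complements of the PhyloSor and UniFrac indices) via a single
    branch-incidence pass, groups assemblages by k-means with Elbow and
    silhouette diagnostics, ordinates them with an evolutionary principal
    components analysis of a Hellinger-transformed branch-length-weighted
    matrix, identifies indicator genera and indicator clades with
    specificity/fidelity statistics over group combinations, partitions
    phylogenetic diversity into group-restricted and shared components,
    and contrasts climatic against geographic classifiability of the
    resulting groups. A synthetic-data generator plants niche-conserved
    or dispersal-limited community assembly so the whole pipeline can be
    exercised and validated without external data.
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
    lme4,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    cluster,
    mclust,
    picante,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
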