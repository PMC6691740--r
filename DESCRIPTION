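Package: cavebiome
Title: Cave Microbiome Diversity, Indicator and Co-Occurrence Network Analysis
Version: 0.1.0
Authors@R: person("Cave", "Biome Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable implementation of the statistical workflow used
    in karst-cave bacteriome surveys spanning four habitat niches (air, water,
    rock, sediment). Provides OTU-table filtering, rarefaction, cumulative sum
    scaling (CSS) and counts-per-million normalization, genus aggregation,
    alpha diversity (observed richness, Chao1, Shannon, Good's coverage), beta
    dissimilarity (Bray-Curtis, weighted UniFrac), Sorensen beta-diversity
    partitioning into turnover and nestedness, PCoA ordination, one-way
    PERMANOVA, environmental vector fitting, Spearman rank-correlation screens,
    IndVal indicator-taxon analysis with permutation tests, permutation-based
    niche-enrichment classification, and Spearman co-occurrence network
    inference with Louvain modules, topology metrics and betweenness-centrality
    keystone ranking. A synthetic-community generator with planted indicator
    taxa, correlation blocks, environmental gradients and a hub taxon supports
    end-to-end recovery testing against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    phyloseq,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
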