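Package: biogeodiv
Title: Continuous Biogeographic Isolation and Assemblage Diversity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies biogeographic isolation among grid-cell species
    assemblages as a continuous quantity and partitions variance in
    taxonomic, phylogenetic and functional diversity between environment
    and isolation. Provides branch-length-based phylogenetic beta
    diversity (the Simpson turnover component and its Sorensen/nestedness
    partition), Faith's phylogenetic diversity, convex-hull functional
    richness and functional beta diversity in trait ordination space,
    non-metric multidimensional scaling with Kruskal stress-1, adjusted
    R-squared variance partitioning with residual-difference mapping,
    phylogenetic signal statistics (Blomberg's K, Fritz-Purvis D), and a
    synthetic-world generator with known ground truth for validating the
    whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    boot,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    phytools,
    picante,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
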