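Package: beescape
Title: Comparative Urban Landscape Genomics for Wild Bee Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for comparative landscape-genomic analysis
    of wild bee populations sampled along urbanisation gradients: a two-tier
    variant filtering ladder with paralog and relatedness screening, adjusted
    expected heterozygosity, Weir-Cockerham FST with locus bootstrapping,
    Mantel tests of isolation by distance, BIC-based cluster search and
    principal coordinates analysis, small-model AIC selection with conditional
    model averaging, genotype-environment association via latent factor ridge
    regression with permutation-derived empirical thresholds and random-forest
    importance ranking, the haplotype-based nSL selection scan with
    frequency-bin normalisation and sweep-region construction, a
    density-preserving position-permutation overlap test, gene mapping, GO
    enrichment with the elim algorithm, Wang semantic similarity with
    best-match averaging, and cross-species convergence permutation tests.
    A seeded synthetic-data generator emulates the sampling design so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    ape,
    geosphere,
    randomForest,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    car,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
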