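Package: pstfst
Title: Phenotypic Versus Neutral Genetic Divergence in Structured Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether phenotypic divergence among wild
    populations exceeds what neutral processes can explain. Implements
    landmark-based geometric morphometrics (generalized Procrustes analysis
    with sliding semilandmarks, relative warps, thin-plate splines,
    repeatability, size-controlled MANCOVA), SNP quality control and
    Weir-Cockerham F_ST with bootstrap confidence intervals, F_ST-outlier
    screening (trimmed chi-square and PCA-Mahalanobis) with consensus
    neutral-set construction, diversity statistics and isolation-by-distance
    tests, BIC-selected k-means clustering with discriminant axes, the
    P_ST trait-divergence index swept over the c/h-squared ratio with
    bootstrap bands, and mitochondrial COI summaries (p-distances, haplotype
    collapse, segregating sites, neighbor-joining trees, minimum-spanning
    haplotype networks). A seeded synthetic-data module generates genotypes,
    landmark configurations, and haplotype alignments with known ground truth
    so every stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    MASS,
    ape,
    igraph,
    geosphere,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
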