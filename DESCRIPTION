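Package: paintpop
Title: Downstream Analysis of Haplotype Painting Profiles for Fine-Scale
    Population Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the downstream analysis layer of haplotype-painting
    population-structure studies: total variation distance (TVD) between
    genome-wide copying profiles and its 1-TVD similarity, asymmetric
    sample-size-corrected permutation tests of group distinguishability
    (including a language-level variant that corrects for ethnic-group
    endogamy), population-relative PI_HAT relatedness pruning with greedy
    removal and duplicate resolution, birthplace assignment and exclusion
    rules from multi-generation records, binned isolation-by-distance
    regression with a river-corridor variant, identity-by-descent sharing
    summaries in centimorgan length bins, harmonisation and calendar
    conversion of admixture-date estimates from multiple dating methods, and
    a piecewise-Ne Wright-Fisher allele-frequency simulator with minor-allele-
    frequency-matched SNP downsampling. A synthetic-data generator with known
    ground truth (Dirichlet copying profiles, planted relatives, distance-
    decaying IBD) makes the whole pipeline testable without genotype data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
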