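Package: rhizodmm
Title: Dirichlet-Multinomial Differential Abundance and Community
    Statistics for Rhizosphere Microbiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical Bayesian Dirichlet-multinomial modelling of
    amplicon (ASV) read-count tables for two-group differential-abundance
    analysis, with a 95% posterior-difference decision rule and log10
    fold-change estimation, as used in plant-microbiome studies of host
    genotype and ploidy effects.  Includes count-table import/filtering
    (TSV and BIOM JSON), Jaccard and Bray-Curtis dissimilarities with
    one-factor PERMANOVA and principal-coordinate analysis, Shannon
    diversity with Welch tests, fixed-effect three-way ANOVA with Tukey
    HSD and planned contrasts for microbiome-feedback phenotype
    experiments, and a Dirichlet-multinomial synthetic-data generator
    with ground-truth records for calibration, power and
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
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
    biomformat,
    emmeans,
    testthat (>= 3.0.0),
    withr
LinkingTo: Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
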