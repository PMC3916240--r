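Package: xcwas
Title: Chromosome X-Wide Association Analysis with Dosage-Compensation Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for association analysis of the non-pseudoautosomal X
    chromosome in quantitative-trait GWAS, where males are hemizygous and
    X-chromosome inactivation makes the female allele coding model-dependent.
    Provides sex-stratified additive association with explicit male genotype
    coding conventions, fixed-effects and sex-differentiated meta-analysis
    with genomic control, a Bayesian comparison of full versus no
    dosage-compensation models from summary statistics, per-sex
    variance-explained and sexual-dimorphism calculators, X-aware genetic
    relationship matrices under three dosage-compensation models with
    average-information REML variance-component estimation, and a synthetic
    genotype/phenotype simulator for validating every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    purrr,
    rlang,
    readr,
    stats,
    tibble,
    tidyr,
    generics,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
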