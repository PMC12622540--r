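Package: plastmap
Title: Reaction-Norm Decomposition and Mixed-Model Mapping of Phenotypic
    Mean and Plasticity in Multi-Environment Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting the trade-off between the phenotypic mean
    and the phenotypic plasticity of a trait scored on a diversity panel
    across several environments. Phenotypes are decomposed by
    Finlay-Wilkinson regression (least-squares and Gibbs-sampled Bayesian
    variants) into genotype mean, linear plasticity (reaction-norm slope)
    and nonlinear plasticity (log residual variance); crossed random-effects
    models give genotype, environment and genotype-by-environment variance
    components, broad-sense heritability and genotype BLUPs; a
    kinship-controlled linear mixed model scans SNPs for association with
    any of the derived sub-phenotypes, with LD-pruned effective-test
    Bonferroni thresholds, per-SNP variance explained and a two-population
    Fst scan; overlapping QTL intervals are condensed into hotspot QTL with
    candidate-gene extraction from GFF3 annotation; environment-response
    models quantify temperature-driven plasticity (DIFF scores, per-genotype
    environment-index regressions, bootstrap summaries); and LASSO plus
    backward-stepwise selection builds minimal marker sets and prediction
    models. A seeded synthetic-data generator emulating a rice mini-core
    collection makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    lme4,
    glmnet,
    MASS,
    jsonlite,
    vcfR,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
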