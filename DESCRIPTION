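Package: poolgp
Title: Genomic Prediction and Association Mapping from Pooled Population
    Allele Frequencies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing genebank collections genotyped at the
    population level by pooled sequencing, where the unit of observation is a
    population-by-marker allele-frequency matrix rather than individual
    genotypes. Provides balanced ANOVA with broad-sense heritability
    indicators and least-squares adjusted means for multi-environment trials,
    a pooled genomic relationship matrix with marker QC, spatial statistics
    (Moran's I, Mantel permutation tests, geodesic distances), mixed-model
    association scans with FDR control and variance-explained summaries,
    RR-BLUP genomic prediction with repeated-holdout cross-validation and
    geographic-origin prediction, four calibration-set optimization
    procedures (stratified genetic/spatial/mixed clustering and CDmean
    exchange) scored against random-set envelopes, and GWAS-informed marker
    selection curves. A synthetic isolation-by-distance generator produces
    spatially structured allele frequencies, QTL-driven phenotypes and
    ground-truth records so every stage can be validated at desk scale.
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
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    emmeans,
    lme4,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
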