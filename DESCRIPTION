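Package: growthgwas
Title: Longitudinal Growth-Curve Phenotyping and Kinship Mixed-Model GWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the temporal genetic analysis of image-based plant
    biomass in inbred diversity panels. Provides simulation of inbred
    genotype panels with block-structured linkage disequilibrium and
    longitudinal logistic-growth phenotypes with planted QTL; robust
    outlier screening; two-step best linear unbiased estimates (BLUEs)
    and one-step variance components with broad-sense heritability;
    logistic growth-curve fitting with inflection points; linkage
    disequilibrium decay with a population-specific background threshold;
    per-day kinship mixed-model genome-wide association scans with
    Benjamini-Hochberg false discovery rate control and QTL trajectories;
    QTL detection-power simulation; and favorable-allele stacking for
    marker-assisted selection.
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
    lme4,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
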