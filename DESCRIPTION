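Package: breedtrial
Title: Heritability and Marker-Association Analysis for Multi-Year Wheat
    Breeding Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of multi-year wheat breeding trials for
    bread-making quality: genotype-by-year analysis of variance, broad-sense
    heritability by the mean-square-ratio and variance-component estimators
    with F-distribution confidence limits, SE-HPLC protein-fraction area
    percentages and composition ratios (Gli:Glu, HMW:LMW, UPP:TPP), trait
    correlation matrices, principal component analysis and principal
    component regression, a quality-filtered single-marker GLM association
    scan with Benjamini-Hochberg control and a multi-environment/multi-model
    consensus rule, and tie-inclusive top-rank selection-overlap evaluation.
    Includes a synthetic breeding-trial generator (phenotypes, SNP panels,
    planted QTL) with a ground-truth record for parameter-recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
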