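Package: apneabiome
Title: Obstructive Sleep Apnea and Gut Microbiota Association Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Population-scale association analysis between obstructive sleep
    apnea (OSA) parameters and the gut microbiota, built as a reusable and
    fully testable pipeline. Computes the apnea-hypopnea index (AHI), oxygen
    desaturation index (ODI) and cumulative nocturnal hypoxia (T90) from
    respiratory event records with per-channel validity rules; derives alpha
    and beta diversity (Shannon index, Bray-Curtis dissimilarity, principal
    coordinate analysis, covariate-adjusted PERMANOVA); runs a covariate-
    adjusted partial Spearman screening/main/extended model cascade with
    Benjamini-Hochberg false discovery control and sensitivity analyses;
    tests effect modification by hemoglobin with bootstrap standard errors;
    multiply imputes missing AHI by predictive mean matching with Rubin
    pooling; detects gut metabolic modules (GMMs) from KEGG-ortholog profiles
    and tests direction-stratified rank enrichment; classifies pairwise
    species co-occurrence with an exact hypergeometric model; and relates hit
    species to blood pressure and glycated hemoglobin. A seeded synthetic
    cohort generator with a planted-effect truth ledger makes every stage
    testable without access to individual-level study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
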