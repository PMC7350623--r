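Package: cnssig
Title: Signature-Based Molecular Diagnosis of Rare Pediatric CNS Tumor Entities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Marker-gene discovery and NanoString-style signature classification
    for four rare pediatric central nervous system tumor entities (CNS NB-FOXR2,
    CNS EFT-CIC, CNS HGNET-MN1 and CNS HGNET-BCOR). Implements resampling-based
    marker selection from expression matrices (quantile normalization, log2
    variance filtering and a repeated balanced-subsample t statistic),
    reading/writing of nCounter RCC count files and CodeSet panels, two-stage
    count normalization (positive-control and housekeeping geometric-mean
    scaling) with reference-fold hybridization QC, reference-anchored
    hierarchical-clustering diagnosis with per-entity signature scores, a
    glioma-contrast re-analysis, one-vs-rest ROC/AUC marker evaluation, and
    seeded synthetic-data generators with planted signatures that give every
    stage a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    limma,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
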