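Package: pdxtrial
Title: Analysis of Patient-Derived Xenograft Preclinical Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for breast-cancer patient-derived xenograft (PDX)
    chemogenomic studies run under a one-animal-per-arm ("1x1x1") design.
    Converts caliper measurements to tumor volumes, computes BestResponse
    and BestAvgResponse, and assigns mRECIST categories (CR/PR/SD/PD);
    provides cohort-level statistics (objective response rates, waterfall
    tables, chemosensitivity classification, doubling-free survival with
    Kaplan-Meier curves and log-rank tests, replicate reproducibility,
    patient-PDX response concordance); scores expression matrices (IQR
    outlier scores, RPPA pathway signature scores, single-sample gene-set
    enrichment, RNA-protein correlation with Benjamini-Hochberg
    correction); computes patient-PDX fidelity statistics (engraftment
    take rate, receptor and intrinsic-subtype concordance, cohort
    composition) from clinical annotation tables; and integrates genomic,
    expression and in vivo evidence into a per-model actionability
    matrix. A synthetic-cohort simulator with a biphasic
    sensitive/resistant growth model makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
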