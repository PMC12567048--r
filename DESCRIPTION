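Package: cryptkin
Title: Cryptic NTRK3 Fusion Scoring and Fusion-Negative NTRK Expression
    Analysis in Cancer Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for studying fusion-negative NTRK1/2/3
    expression in bulk cancer cohorts (colorectal cancer in particular):
    expression preprocessing (winsorization, zero-to-one normalization,
    cohort pooling with bias checks, median dichotomization, rank-based
    Gaussian normalization), inference of cryptic NTRK3 fusions from
    copy-number segments and expression via the additive NFS1/NFS2 fusion
    scores, deregulation regressions of expression on methylation, copy
    number and fusion score, a clinicopathological association battery with
    Benjamini-Hochberg control, a weighted Kolmogorov-Smirnov gene-set
    enrichment engine with permutation null, and Fisher over-representation
    with volcano export. A two-cohort synthetic cancer-cohort generator with
    planted deletion-plus-overexpression fusions makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
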