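Package: wcps
Title: Weighted Change-Point Statistics for Heterogeneous Differential
    Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Nonparametric detection of differential gene expression that is
    confined to a subset of case (cancer) samples, based on a weighted
    modified Kolmogorov change-point scan of the combined expression
    sequence.  Provides the unweighted change-point statistic (NPCPS), its
    right-bound-compensated weighted form (WCPS), classical outlier-profile
    comparator statistics (t, COPA, OS, ORT, MOST, LRS), a Monte Carlo
    harness for change-point recovery, miss-rate and ROC/AUC studies, and a
    pipeline for gene-by-sample expression matrices (probe collapsing,
    ranking, per-sample DGE flagging).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
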