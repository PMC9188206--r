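Package: derscore
Title: Rank-Based Scoring of YAP1-TEAD Transcriptional Activity in Tumor Cohorts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Derives a directional YAP1-TEAD effector signature from oriented
    perturbation differential-expression tables, scores per-sample pathway
    activity with the difference-of-effector-ranks (deR) statistic on
    fractional ranks, calls genetic alterations from GISTIC-style thresholded
    copy-number and MAF-style mutation tables, computes alteration prevalence
    and genotype-score association rankings, and provides the small
    pharmacodynamic and efficacy arithmetic (tumor volume, growth inhibition,
    regression, comparative-Ct quantification) used alongside such scores.
    Includes seeded simulators for perturbation experiments and multi-omic
    cohorts with a planted latent activity level, so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
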