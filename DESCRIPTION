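Package: reometa
Title: Rank-Based Gene-Pair Risk Classification and Metastasis
    Reclassification for Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Individual-level risk classification of tumor expression
    profiles from within-sample relative expression orderings (REOs) of
    signature gene pairs under configurable k-of-n voting rules, with
    calibration of strict voting thresholds against an expected relapse
    interval. Includes the downstream analyses such a classifier enables:
    Kaplan-Meier, log-rank, Cox and concordance-index survival evaluation;
    reclassification of occult-metastasis states; coefficient-of-variation
    filtered differential expression with Benjamini-Hochberg control;
    proliferation scoring and gene-set enrichment; somatic mutation and
    copy-number lesion frequency and burden comparisons; expression-copy
    number correlation; and construction of directed regulator-target
    driver networks. A seeded synthetic-cohort generator provides
    expression, clinical, mutation, copy-number and network layers with
    known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
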