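Package: admega
Title: Cross-Study Mega-Analysis of Bulk Expression with Cell-Type
    Proportion Correction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint re-analysis (mega-analysis) of multi-study bulk brain
    expression data: cross-platform integration with quantile normalization
    and background-guided filtering, marker gene profile (MGP) estimation of
    relative cell-type abundance, per-gene random-study-intercept linear
    mixed models with and without MGP correction, likelihood-ratio tests
    with Benjamini-Hochberg FDR, leave-one-study-out jackknife gene ranking,
    and threshold-free precision-recall gene-set enrichment. Includes a
    synthetic multi-study cohort generator with known cell-type composition
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    lme4,
    limma,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
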