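Package: wescore
Title: Weighted Expression Scoring and DDR Phenotype Clustering for Tumor Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores transcriptional regulation of DNA damage response (DDR)
    pathways from bulk expression matrices using essentiality-weighted
    per-pathway aggregation of gene z-scores (WE scores), partitions samples
    into DDR Low / Intermediate / High phenotypes by k-means with an
    elbow-based choice of k, and tests cluster associations with categorical
    labels (Monte-Carlo chi-square with Pearson residuals) and continuous
    scores (pairwise Wilcoxon tests). Includes a synthetic-cohort generator
    with planted cluster structure for end-to-end validation.
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
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
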