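Package: methpanel
Title: Discovery and Evaluation of Cancer-Specific DNA Methylation Biomarker Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for discovering diagnostic DNA methylation
    biomarker panels from probe-level beta-value matrices. Implements
    recursively partitioned beta-mixture clustering of tumor methylomes on the
    most variable probes, pairwise differential-methylation testing with
    Benjamini-Hochberg adjustment, intersection-based selection of
    cancer-specific hypermethylated probes under strict and relaxed criteria,
    greedy assembly of small diagnostic panels with a max-beta call rule, and
    panel evaluation on primary tumors, independent verification cohorts,
    liver metastases and cell-free DNA. Ships a synthetic multi-project cohort
    generator with planted ground truth (methylation subtypes, marker probes,
    metastases, tumor/leukocyte cfDNA mixtures) so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
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
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
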