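Package: agestable
Title: Discovery and Validation of Age-Invariant Reference Genes from
    Bulk RNA-Seq and RT-qPCR Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate reference (housekeeping) genes whose
    expression is invariant across the lifespan in multi-tissue bulk
    RNA-seq cohorts. Counts are normalized two ways (transcripts per
    million and trimmed-mean-of-M-values scaled counts per million) and
    genes are screened per tissue through seven sequential criteria:
    continuous expression, low log2 standard deviation, no outlying
    samples, medium-to-high expression, low percent coefficient of
    variation, no age correlation under a fractional (alpha/n)
    significance threshold, and validation in an independent cohort.
    Per-tissue lists are intersected into pan-tissue candidates.
    Cycle-threshold (Ct) tables are scored with the geNorm, NormFinder,
    BestKeeper and comparative delta-Ct stability algorithms and
    aggregated into a RefFinder composite rank. Candidate sets are
    characterized by promoter CpG-island enrichment, transcript length
    and GC comparisons, and Fisher's-exact gene-set enrichment against a
    custom background. A negative-binomial multi-tissue cohort simulator
    with planted gene classes supports end-to-end testing and power
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    tibble,
    tidyr,
    utils
Suggests:
    edgeR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
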