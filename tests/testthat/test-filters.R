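log2_tbl <- function(m, ...) wide_counts(m, ...) # log2 values, same shape

test_that("continuous-expression filter demands a value in every sample", {
  x <- log2_expression(wide_counts(matrix(c(2, 4, 8, 0, 1, 2), nrow = 2, byrow = TRUE),
                                   genes = c("a", "b")))
  expect_equal(unname(filter_continuous(x)), c(TRUE, FALSE))
  empty <- tibble::tibble(gene_id = character())
  expect_error(filter_continuous(empty), "no samples")
})

test_that("low-variance filter uses the sample SD with a strict cutoff", {
  x <- log2_tbl(matrix(c(2, 4, 3, 3, 3, 3, 3.0, 3.5, 2.5, NA, 2, 2),
                       nrow = 4, byrow = TRUE), genes = letters[1:4])
  st <- gene_stats(x, ages = c(1, 2, 3))
  expect_equal(st$sd_log2[1], sd1(c(2, 4, 3)), tolerance = 1e-12)
  flags <- filter_low_variance(st)
  expect_true(flags[["b"]])  # constant gene, SD 0
  expect_true(flags[["c"]])  # sd(c(3, 3.5, 2.5)) = 0.5
  expect_false(flags[["d"]]) # NA stats fail by construction
  two <- gene_stats(log2_tbl(matrix(c(2, 4), nrow = 1), genes = "g"), ages = c(1, 2))
  expect_equal(two$sd_log2, sd1(c(2, 4)), tolerance = 1e-12) # 1.414 -> fail
  expect_false(filter_low_variance(two)[["g"]])
})

test_that("outlier filter bounds |deviation from the mean| at 2, inclusively", {
  x <- log2_tbl(matrix(c(3, 3, 6, 3, 3, 7, 5, 5, 5), nrow = 3, byrow = TRUE),
                genes = c("boundary", "outlier", "constant"))
  flags <- filter_no_outliers(x)
  expect_true(flags[["boundary"]])   # mean 4, max dev exactly 2
  expect_false(flags[["outlier"]])   # mean 13/3, dev 8/3 > 2
  expect_true(flags[["constant"]])
})

test_that("expression filter compares gene means to the pooled background", {
  x <- log2_tbl(matrix(c(10, 10, 2, 2), nrow = 2, byrow = TRUE), genes = c("A", "B"))
  expect_equal(background_mean(x), 6)
  st <- gene_stats(x, ages = c(1, 2))
  flags <- filter_expression_level(st, background_mean(x))
  expect_true(flags[["A"]])
  expect_false(flags[["B"]])

  single <- log2_tbl(matrix(c(4, 5), nrow = 1), genes = "only")
  st1 <- gene_stats(single, ages = c(1, 2))
  expect_true(filter_expression_level(st1, background_mean(single))[["only"]])

  same <- log2_tbl(matrix(7, nrow = 3, ncol = 2), genes = c("a", "b", "c"))
  st2 <- gene_stats(same, ages = c(1, 2))
  expect_true(all(filter_expression_level(st2, background_mean(same))))

  allzero <- log2_expression(wide_counts(matrix(0, nrow = 2, ncol = 2)))
  expect_error(background_mean(allzero), "background")
})

test_that("percent-CV filter is computed on the log2 scale", {
  x <- log2_tbl(matrix(c(9, 11, 5, 8, 6, 6, -1, 0.5), nrow = 4, byrow = TRUE),
                genes = c("pass", "fail", "constant", "negmean"))
  st <- gene_stats(x, ages = c(1, 2))
  expect_equal(st$cv_pct[1], sd1(c(9, 11)) / 10 * 100, tolerance = 1e-12) # 14.14
  expect_equal(st$cv_pct[2], sd1(c(5, 8)) / 6.5 * 100, tolerance = 1e-12) # 32.6
  flags <- filter_cv(st)
  expect_equal(unname(flags), c(TRUE, FALSE, TRUE, FALSE))
})

test_that("age screen removes correlated genes at the fractional threshold", {
  ages <- c(3, 6, 9, 12, 15, 18)
  x <- log2_tbl(rbind(5 + 0.1 * ages, rep(4, 6)), genes = c("linear", "flat"))
  st <- gene_stats(x, ages = ages)
  res <- filter_age_correlation(st, n_tissues = 1L, alpha = 0.05)
  expect_false(res$keep[res$gene_id == "linear"]) # r = 1, p ~ 0 -> removed
  expect_true(res$keep[res$gene_id == "flat"])    # zero variance -> kept
  expect_true(is.na(res$cor_p[res$gene_id == "flat"]))
  expect_equal(unique(filter_age_correlation(st, n_tissues = 17L)$threshold),
               0.05 / 17, tolerance = 1e-12)
  expect_equal(round(0.05 / 17, 7), 0.0029412)
  expect_error(filter_age_correlation(st, n_tissues = 0L), ">= 1")
})

test_that("family-wise discard probability matches its closed form and oracle", {
  expect_equal(familywise_discard_probability(0.05, 1), 0.05)
  expect_equal(familywise_discard_probability(0, 5), 0)
  p17 <- familywise_discard_probability(0.05, 17)
  expect_equal(p17, 0.5819, tolerance = 1e-4)
  expect_equal(round(100 * p17), 58)
  for (n in c(1, 3, 7, 10)) {
    for (alpha in c(0.05, 0.2)) {
      expect_equal(familywise_discard_probability(alpha, n),
                   familywise_bruteforce(alpha, n), tolerance = 1e-12)
    }
  }
  expect_error(familywise_discard_probability(1.2, 3), "alpha")
})

cohort <- simulate_cohort(cohort_config(seed = 1L))
pipe <- run_filter_pipeline(cohort$counts, cohort$metadata, cohort$annotation)

test_that("planted classes are removed at their designed steps", {
  truth <- cohort$truth
  joined <- dplyr::left_join(pipe$filters, truth[c("gene_id", "class_label")],
                             by = "gene_id")
  drop <- joined[joined$class_label == "dropout", ]
  expect_true(all(!drop$f1))
  spiked <- joined[joined$class_label == "outlier_spiked", ]
  expect_true(all(!spiked$f3)) # eliminated at or before the outlier step
  low <- joined[joined$class_label == "stable_low", ]
  expect_true(all(!low$f4))
  trend <- joined[joined$class_label == "age_trend", ]
  expect_true(all(!trend$f6))
  stable <- joined[joined$class_label == "stable_high", ]
  expect_gte(mean(stable$final), 0.9)
})

test_that("survivor sets are monotonically nested and counts non-increasing", {
  fm <- as.matrix(pipe$filters[paste0("f", 1:6)])
  for (k in 2:6) expect_true(all(fm[, k] <= fm[, k - 1]))
  counts_by_tissue <- split(pipe$survivor_counts, pipe$survivor_counts$tissue)
  for (tbl in counts_by_tissue) {
    expect_true(all(diff(tbl$n_survivors[order(tbl$step)]) <= 0))
  }
})

test_that("a gene must pass under both normalizations to survive a step", {
  joined <- dplyr::inner_join(
    pipe$flags[pipe$flags$normalization == "TPM", ],
    pipe$flags[pipe$flags$normalization == "TMM", ],
    by = c("gene_id", "tissue"), suffix = c("_tpm", "_tmm")
  )
  combined <- dplyr::left_join(joined, pipe$filters, by = c("gene_id", "tissue"))
  # cumulative survivor flag implies raw pass under both normalizations
  for (k in 1:6) {
    ck <- combined[[paste0("f", k)]]
    expect_true(all(combined[[paste0("f", k, "_tpm")]][ck]))
    expect_true(all(combined[[paste0("f", k, "_tmm")]][ck]))
  }
  # and the normalizations genuinely disagree somewhere, so the
  # intersection is doing work
  disagree <- mapply(
    function(a, b) xor(a, b),
    combined[paste0("f", 1:6, "_tpm")], combined[paste0("f", 1:6, "_tmm")]
  )
  expect_gt(sum(disagree), 0)
})

test_that("pipeline results are invariant to gene and sample order", {
  set.seed(9)
  counts <- cohort$counts[sample(nrow(cohort$counts)), ]
  counts <- counts[, c(1L, 1L + sample(ncol(counts) - 1L))]
  pipe2 <- run_filter_pipeline(counts, cohort$metadata, cohort$annotation)
  expect_identical(
    lapply(final_gene_lists(pipe), sort),
    lapply(final_gene_lists(pipe2), sort)
  )
  s1 <- dplyr::arrange(pipe$stats, gene_id, tissue, normalization)
  s2 <- dplyr::arrange(pipe2$stats, gene_id, tissue, normalization)
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("pan-tissue intersection is a plain set intersection", {
  expect_equal(pan_tissue_intersection(list(t1 = c("A", "B"), t2 = c("B", "C"))), "B")
  expect_equal(pan_tissue_intersection(list(t1 = c("A", "B"), t2 = c("B", "A"))),
               c("A", "B"))
  expect_equal(pan_tissue_intersection(list(t1 = character(), t2 = c("B"))),
               character())
  expect_error(pan_tissue_intersection(list()), "at least one")
  pan <- pan_tissue_intersection(pipe)
  finals <- final_gene_lists(pipe)
  expect_true(all(vapply(finals, function(g) all(pan %in% g), logical(1))))
})

test_that("validation passes flat candidates and rejects trending ones", {
  val <- simulate_cohort(cohort_config(seed = 77L))
  res <- validate_candidates(pipe, val$counts, val$metadata, val$annotation)
  truth <- cohort$truth
  stable <- truth$gene_id[truth$class_label == "stable_high"]
  res_stable <- res[res$gene_id %in% stable, ]
  expect_gte(mean(res_stable$pass), 0.9)
  # a candidate absent from the validation matrix fails as unmeasured
  val_small <- val$counts[val$counts$gene_id != res$gene_id[1], ]
  res2 <- validate_candidates(pipe, val_small, val$metadata, val$annotation)
  miss <- res2[res2$gene_id == res$gene_id[1], ]
  expect_true(all(!miss$pass))
  expect_true(all(miss$reason == "not measured"))
})

test_that("stage subset over all stages reproduces steps 1-4", {
  stages <- unique(cohort$metadata$stage)
  sub <- stage_subset_analysis(cohort$counts, cohort$metadata, cohort$annotation,
                               stages = stages)
  merged <- dplyr::inner_join(
    sub$filters, pipe$filters,
    by = c("gene_id", "tissue"), suffix = c("_sub", "_full")
  )
  for (k in 1:4) {
    expect_identical(merged[[paste0("f", k, "_sub")]],
                     merged[[paste0("f", k, "_full")]])
  }
  expect_error(
    stage_subset_analysis(cohort$counts, cohort$metadata, cohort$annotation,
                          stages = "larval"),
    "not present"
  )
})

test_that("young-variable genes show elevated %CV in the young stage only", {
  young <- stage_subset_analysis(cohort$counts, cohort$metadata,
                                 cohort$annotation, stages = "young")
  old <- stage_subset_analysis(cohort$counts, cohort$metadata,
                               cohort$annotation, stages = "old")
  yv <- cohort$truth$gene_id[cohort$truth$class_label == "young_variable"]
  get_cv <- function(res) {
    st <- res$stats[res$stats$normalization == "TPM" & res$stats$gene_id %in% yv, ]
    tapply(st$cv_pct, st$gene_id, mean)
  }
  cv_y <- get_cv(young)
  cv_o <- get_cv(old)
  expect_gte(mean(cv_y > cv_o, na.rm = TRUE), 0.9)
})

test_that("size-matched stage control uses exactly n samples, reproducibly", {
  ctl1 <- stage_subset_analysis(cohort$counts, cohort$metadata, cohort$annotation,
                                stages = NULL, control_n = 10L, seed = 4L)
  ctl2 <- stage_subset_analysis(cohort$counts, cohort$metadata, cohort$annotation,
                                stages = NULL, control_n = 10L, seed = 4L)
  expect_identical(ctl1$samples_used, ctl2$samples_used)
  per_tissue <- table(sub("_.*", "", ctl1$samples_used))
  expect_true(all(per_tissue == 10L))
})

test_that("classical reference genes are classified per tissue", {
  finals <- final_gene_lists(pipe)
  valid_gene <- finals[[1]][1]
  trend_gene <- cohort$truth$gene_id[cohort$truth$class_label == "age_trend"][1]
  res <- classify_reference_genes(c(valid_gene, trend_gene, "ghost"), pipe)
  expect_equal(
    res$status[res$gene_id == valid_gene & res$tissue == names(finals)[1]],
    "valid"
  )
  trend_rows <- res[res$gene_id == trend_gene, ]
  expect_true(all(trend_rows$status == "invalid"))
  expect_true(all(!is.na(trend_rows$failed_at)))
  expect_true(all(res$status[res$gene_id == "ghost"] == "not assessable"))
  empty <- classify_reference_genes(character(), pipe)
  expect_identical(nrow(empty), 0L)
})

test_that("tidy and glance summarise a pipeline", {
  td <- generics::tidy(pipe)
  expect_identical(nrow(td), nrow(pipe$filters) * 6L)
  expect_true(all(c("gene_id", "tissue", "step", "pass") %in% names(td)))
  gl <- generics::glance(pipe)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$n_genes, 600L)
  expect_identical(gl$n_tissues, 3L)
})

test_that("an all-same-age tissue is rejected by the screen", {
  coh <- simulate_cohort(small_config(seed = 2L))
  meta <- coh$metadata
  meta$age_months <- 6
  expect_error(run_filter_pipeline(coh$counts, meta, coh$annotation), "one age")
})
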