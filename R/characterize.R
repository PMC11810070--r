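# Feature and enrichment statistics contrasting age-invariant with
# age-variant gene sets: promoter CpG-island proportions per filter step,
# transcript-length / GC comparisons, Welch group tests, Fisher's-exact
# gene-set enrichment on a custom background.

# sample odds ratio ad/bc; NA on any zero cell (documented convention), with
# the Haldane-Anscombe (+0.5 to every cell) value alongside.
odds_ratio_cells <- function(a, b, c, d) {
  or <- ifelse(b == 0 | c == 0 | a == 0 | d == 0, NA_real_, (a * d) / (b * c))
  or_h <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  list(odds_ratio = or, odds_ratio_haldane = or_h)
}

fisher_p <- function(a, b, c, d) {
  vapply(seq_along(a), function(i) {
    fisher.test(matrix(c(a[i], c[i], b[i], d[i]), nrow = 2L))$p.value
  }, numeric(1))
}

#' CpG-island proportion among survivors of each filter step
#'
#' For every tissue and cumulative step 1-6, the fraction of surviving genes
#' whose promoter is CGI-positive (genes of unknown status excluded), with a
#' two-sided Fisher's exact test of CGI status x survival at that step
#' against the step-1 background of the same tissue. Cross-tissue mean and
#' SD of the proportions are returned alongside.
#'
#' @param pipeline an `rg_pipeline`.
#' @param annotation annotation tibble with `cgi_status`
#'   (`"CGI+"`/`"CGI-"`/`"unknown"`).
#' @return list with `by_tissue` (tissue, step, n_survivors, n_cgi,
#'   prop_cgi, a-d, odds_ratio, odds_ratio_haldane, p_value) and `summary`
#'   (step, mean_prop, sd_prop).
#' @export
cgi_proportion_by_filter <- function(pipeline, annotation) {
  stopifnot(inherits(pipeline, "rg_pipeline"))
  status <- setNames(annotation$cgi_status, annotation$gene_id)
  known <- names(status)[status %in% c("CGI+", "CGI-")]
  if (!length(known)) abort("no gene has a known CGI status")

  rows <- list()
  for (tis in pipeline$tissues) {
    sub <- pipeline$filters %>% filter(.data$tissue == .env$tis)
    base_genes <- intersect(sub$gene_id[sub$f1], known)
    base_pos <- sum(status[base_genes] == "CGI+")
    for (k in 1:6) {
      surv <- intersect(sub$gene_id[sub[[paste0("f", k)]]], known)
      n_pos <- sum(status[surv] == "CGI+")
      a <- n_pos
      b <- length(surv) - n_pos
      c_ <- base_pos - n_pos
      d <- (length(base_genes) - base_pos) - b
      or <- odds_ratio_cells(a, b, c_, d)
      rows[[paste(tis, k)]] <- tibble(
        tissue = tis, step = k,
        n_survivors = length(surv), n_cgi = n_pos,
        prop_cgi = if (length(surv)) n_pos / length(surv) else NA_real_,
        a = a, b = b, c = c_, d = d,
        odds_ratio = or$odds_ratio,
        odds_ratio_haldane = or$odds_ratio_haldane,
        p_value = if (length(surv)) fisher_p(a, b, c_, d) else NA_real_
      )
    }
  }
  by_tissue <- bind_rows(rows)
  summary <- by_tissue %>%
    group_by(.data$step) %>%
    summarise(mean_prop = mean(.data$prop_cgi, na.rm = TRUE),
              sd_prop = sd(.data$prop_cgi), .groups = "drop")
  list(by_tissue = by_tissue, summary = summary)
}

#' Compare a numeric annotation feature between two gene sets
#'
#' Reports per-set medians and means and a two-sided test for a shift
#' (Mann-Whitney U by default, suited to skewed length distributions; Welch
#' t available).
#'
#' @param annotation annotation tibble.
#' @param genes_a,genes_b character vectors of gene ids (non-empty).
#' @param field numeric annotation column, e.g. `"transcript_length_median"`
#'   or `"gc_fraction"`.
#' @param test `"wilcoxon"` or `"welch"`.
#' @return one-row tibble: field, n_a, n_b, median_a, median_b, mean_a,
#'   mean_b, direction, statistic, p_value, test.
#' @export
feature_comparison <- function(annotation, genes_a, genes_b, field,
                               test = c("wilcoxon", "welch")) {
  test <- match.arg(test)
  if (!length(genes_a) || !length(genes_b)) abort("both gene sets must be non-empty")
  if (!field %in% names(annotation)) abort(sprintf("no annotation column '%s'", field))
  va <- annotation[[field]][match(genes_a, annotation$gene_id)]
  vb <- annotation[[field]][match(genes_b, annotation$gene_id)]
  va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
  if (!is.numeric(va) || !length(va) || !length(vb)) {
    abort(sprintf("field '%s' has no numeric values in one of the sets", field))
  }
  if (sd(c(va, vb)) == 0) {
    warn(sprintf("'%s' is constant across both sets; no shift testable", field))
    stat <- NA_real_; p <- 1
  } else {
    ht <- if (test == "wilcoxon") {
      suppressWarnings(wilcox.test(va, vb))
    } else {
      t.test(va, vb)
    }
    stat <- unname(ht$statistic); p <- ht$p.value
  }
  med_a <- median(va); med_b <- median(vb)
  tibble(
    field = field, n_a = length(va), n_b = length(vb),
    median_a = med_a, median_b = med_b,
    mean_a = mean(va), mean_b = mean(vb),
    direction = dplyr::case_when(
      med_a < med_b ~ "A lower",
      med_a > med_b ~ "A higher",
      TRUE ~ "no shift"
    ),
    statistic = stat, p_value = p, test = test
  )
}

#' Welch two-sample t-test between two groups of values
#'
#' @param values numeric vector (e.g. percent CV or |age correlation| of
#'   classical reference genes).
#' @param group two-level grouping vector aligned with `values`.
#' @return one-row tibble: group levels and means, t statistic, df, p_value.
#' @export
group_compare <- function(values, group) {
  group <- as.character(group)
  keep <- !is.na(values) & !is.na(group)
  values <- values[keep]; group <- group[keep]
  lev <- unique(group)
  if (length(lev) != 2L) abort("exactly two groups are required")
  if (any(table(group) < 2L)) abort("each group needs at least 2 values")
  ht <- t.test(values[group == lev[1L]], values[group == lev[2L]])
  tibble(
    group_a = lev[1L], group_b = lev[2L],
    mean_a = unname(ht$estimate[1L]), mean_b = unname(ht$estimate[2L]),
    statistic = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value
  )
}

#' Fisher's-exact gene-set enrichment on a custom background
#'
#' For every set: a 2x2 table of set membership x query membership over the
#' background (sets and query intersected with the background first), a
#' two-sided Fisher's exact p-value (minimum-likelihood convention), the
#' sample odds ratio ad/bc (NA on a zero cell, Haldane-corrected value
#' alongside), and Bonferroni adjustment over the collection.
#'
#' @param query character vector of gene ids (must lie in `background`).
#' @param sets named list of character vectors, or a tibble with `set_id`
#'   and `gene_id`.
#' @param background character vector of gene ids (e.g. genes expressed at
#'   least once in every tissue, exported by the pipeline).
#' @return tibble: set_id, set_size, overlap, a-d, odds_ratio,
#'   odds_ratio_haldane, p_value, p_adjusted.
#' @export
gene_set_enrichment <- function(query, sets, background) {
  if (!length(background)) abort("background must be non-empty")
  background <- unique(background)
  query <- unique(query)
  outside <- setdiff(query, background)
  if (length(outside)) {
    abort(sprintf("query gene(s) outside background: %s",
                  paste(head(outside, 5L), collapse = ", ")))
  }
  if (is.data.frame(sets)) sets <- split(sets$gene_id, sets$set_id)
  if (!length(sets)) abort("no gene sets supplied")
  n_bg <- length(background)
  rows <- purrr::imap(sets, function(genes, id) {
    s <- intersect(unique(genes), background)
    a <- length(intersect(s, query))
    b <- length(query) - a
    c_ <- length(s) - a
    d <- n_bg - a - b - c_
    or <- odds_ratio_cells(a, b, c_, d)
    tibble(
      set_id = id, set_size = length(s), overlap = a,
      a = a, b = b, c = c_, d = d,
      odds_ratio = or$odds_ratio, odds_ratio_haldane = or$odds_ratio_haldane,
      p_value = fisher_p(a, b, c_, d)
    )
  })
  out <- bind_rows(rows)
  out$p_adjusted <- p.adjust(out$p_value, method = "bonferroni")
  out
}

#' Read a GMT-style gene-set file
#'
#' Tab-separated lines: set_id, description, then gene ids.
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) abort(sprintf("GMT line %d has fewer than 3 fields", bad[1L]))
  setNames(
    lapply(fields, function(f) unique(f[-(1:2)])),
    vapply(fields, `[[`, character(1), 1L)
  )
}

#' Correlation between RNA-seq percent CV and the RefFinder composite
#'
#' Pearson correlation across the genes shared between a stability table
#' and an RNA-seq statistics table.
#'
#' @param stability tibble with `gene_id` and `reffinder_score` (e.g. from
#'   [rank_stability()]).
#' @param stats tibble with `gene_id` and `cv_pct` (e.g. the TPM rows of a
#'   pipeline's `stats` for one tissue).
#' @return one-row tibble: n_genes, estimate, statistic, p_value.
#' @export
score_cv_correlation <- function(stability, stats) {
  merged <- dplyr::inner_join(
    stability %>% select("gene_id", "reffinder_score"),
    stats %>% select("gene_id", "cv_pct"),
    by = "gene_id"
  ) %>% filter(!is.na(.data$cv_pct), !is.na(.data$reffinder_score))
  if (nrow(merged) < 3L) abort("need at least 3 shared genes")
  ht <- stats::cor.test(merged$cv_pct, merged$reffinder_score, method = "pearson")
  tibble(
    n_genes = nrow(merged), estimate = unname(ht$estimate),
    statistic = unname(ht$statistic), p_value = ht$p.value
  )
}
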