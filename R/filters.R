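# The seven-step age-invariant screen. Steps 1-6 run per tissue under BOTH
# normalizations (TPM, TMM-scaled CPM); a gene survives a step only if it
# passes under both. Step 7 validates candidates on an independent cohort.

#' Filtering thresholds and options
#'
#' @param alpha significance level for the age-correlation screens.
#' @param sd_max log2-SD cutoff for the low-variance filter (strict `<`).
#' @param outlier_delta max allowed |log2 deviation| from the gene mean
#'   (inclusive).
#' @param cv_max_pct percent-CV cutoff (inclusive), computed on log2 values.
#' @param min_library sample depth threshold in counts (inclusive pass).
#' @param correlation_method correlation used in the discovery age screen
#'   (`"pearson"` per the screen's definition; `"spearman"` available).
#' @param cv_scale `"log2"` (percent CV of log2 values, the screen's
#'   definition) or `"linear"`.
#' @param background `"filter1"` (pooled mean of all log2 values over genes
#'   passing the continuous-expression filter) or `"any_nonzero"` (genes with
#'   at least one nonzero sample, zero-containing genes contributing their
#'   nonzero values).
#' @return a list of class `filter_context`.
#' @export
filter_context <- function(alpha = 0.05, sd_max = 1, outlier_delta = 2,
                           cv_max_pct = 20, min_library = 5e6,
                           correlation_method = c("pearson", "spearman"),
                           cv_scale = c("log2", "linear"),
                           background = c("filter1", "any_nonzero")) {
  assert_scalar_number(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  assert_scalar_number(sd_max, "sd_max", lower = 0)
  assert_scalar_number(outlier_delta, "outlier_delta", lower = 0)
  assert_scalar_number(cv_max_pct, "cv_max_pct", lower = 0)
  ctx <- list(
    alpha = alpha, sd_max = sd_max, outlier_delta = outlier_delta,
    cv_max_pct = cv_max_pct, min_library = min_library,
    correlation_method = match.arg(correlation_method),
    cv_scale = match.arg(cv_scale),
    background = match.arg(background)
  )
  class(ctx) <- "filter_context"
  ctx
}

#' Per-gene summary statistics on a log2 expression table
#'
#' All statistics are NA for a gene with any zero-expression (NA log2)
#' sample: the screen's statistics are only defined on fully observed genes.
#' `cv_pct` is the percent coefficient of variation of the log2 values
#' (`sd / mean * 100`), NA when the mean is not positive.
#'
#' @param log2_tbl tibble from [log2_expression()].
#' @param ages numeric vector of ages (months), aligned to the sample
#'   columns.
#' @param method correlation method for the age association.
#' @return tibble: gene_id, n_samples, mean_log2, sd_log2, cv_pct, age_slope,
#'   cor_coef, cor_p.
#' @export
gene_stats <- function(log2_tbl, ages, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m <- as_gene_matrix(log2_tbl)
  if (length(ages) != ncol(m)) abort("ages must align with the sample columns")
  n <- ncol(m)
  complete <- rowSums(is.na(m)) == 0L

  mean_log2 <- sd_log2 <- cv_pct <- slope <- r <- p <- rep(NA_real_, nrow(m))
  if (any(complete)) {
    mc <- m[complete, , drop = FALSE]
    mu <- rowMeans(mc)
    sdv <- row_sds(mc)
    mean_log2[complete] <- mu
    sd_log2[complete] <- sdv
    cv_pct[complete] <- ifelse(mu > 0, sdv / mu * 100, NA_real_)
    if (stats::var(ages) > 0 && n >= 3L) {
      centered_age <- ages - mean(ages)
      slope[complete] <- as.vector(mc %*% centered_age) / sum(centered_age^2)
      rr <- row_cor(mc, ages, method = method)
      r[complete] <- rr
      p[complete] <- cor_pvalue(rr, n)
    }
  }
  tibble(
    gene_id = rownames(m), n_samples = n, mean_log2 = mean_log2,
    sd_log2 = sd_log2, cv_pct = cv_pct, age_slope = slope,
    cor_coef = r, cor_p = p
  )
}

#' Step 1: continuous expression
#'
#' A gene passes when it has nonzero expression (a defined log2 value) in
#' every sample of the tissue.
#'
#' @inheritParams gene_stats
#' @return logical vector named by gene.
#' @export
filter_continuous <- function(log2_tbl) {
  m <- as_gene_matrix(log2_tbl)
  if (ncol(m) == 0L) abort("no samples")
  setNames(rowSums(is.na(m)) == 0L, rownames(m))
}

#' Step 2: low variance (log2 SD strictly below the cutoff)
#'
#' @param stats tibble from [gene_stats()].
#' @param sd_max cutoff (log2 units), strict `<`.
#' @return logical vector named by gene; NA statistics fail.
#' @export
filter_low_variance <- function(stats, sd_max = 1) {
  setNames(!is.na(stats$sd_log2) & stats$sd_log2 < sd_max, stats$gene_id)
}

#' Step 3: no outlying samples
#'
#' Every log2 value must lie within `outlier_delta` units of the gene's mean
#' (inclusive).
#'
#' @inheritParams gene_stats
#' @param outlier_delta allowed |deviation| in log2 units.
#' @return logical vector named by gene; genes with NA values fail.
#' @export
filter_no_outliers <- function(log2_tbl, outlier_delta = 2) {
  m <- as_gene_matrix(log2_tbl)
  dev <- abs(m - rowMeans(m))
  ok <- apply(dev, 1L, max) <= outlier_delta
  ok[is.na(ok)] <- FALSE
  setNames(ok, rownames(m))
}

#' Pooled background mean for the expression-level filter
#'
#' Mean of all log2 values pooled over the background genes of the tissue
#' (by default those passing the continuous-expression step, the only genes
#' whose log2 values are fully defined).
#'
#' @inheritParams gene_stats
#' @param background `"filter1"` or `"any_nonzero"`.
#' @return scalar background mean (log2 units).
#' @export
background_mean <- function(log2_tbl, background = c("filter1", "any_nonzero")) {
  background <- match.arg(background)
  m <- as_gene_matrix(log2_tbl)
  keep <- if (background == "filter1") {
    rowSums(is.na(m)) == 0L
  } else {
    rowSums(!is.na(m)) > 0L
  }
  if (!any(keep)) abort("no background genes: every gene has a zero-count sample")
  mean(m[keep, , drop = FALSE], na.rm = TRUE)
}

#' Step 4: medium-to-high expression
#'
#' A gene passes when its mean log2 expression is at or above the tissue's
#' pooled background mean (inclusive).
#'
#' @param stats tibble from [gene_stats()].
#' @param background scalar from [background_mean()].
#' @return logical vector named by gene.
#' @export
filter_expression_level <- function(stats, background) {
  assert_scalar_number(background, "background")
  setNames(!is.na(stats$mean_log2) & stats$mean_log2 >= background, stats$gene_id)
}

#' Step 5: low percent coefficient of variation
#'
#' Percent CV of the log2 values (SD / mean x 100) must not exceed
#' `cv_max_pct` (inclusive). Genes whose mean log2 is not positive cannot
#' satisfy a percentage bound and fail.
#'
#' @param stats tibble from [gene_stats()].
#' @param cv_max_pct cutoff in percent.
#' @return logical vector named by gene.
#' @export
filter_cv <- function(stats, cv_max_pct = 20) {
  setNames(!is.na(stats$cv_pct) & stats$cv_pct <= cv_max_pct, stats$gene_id)
}

#' Step 6: no correlation with age under the fractional threshold
#'
#' A gene is removed when its age-correlation p-value is at or below
#' `alpha / n`, where `n` is the number of tissues in which the gene passed
#' steps 1-4; it is kept otherwise. A zero-variance gene has an undefined
#' correlation, which is no evidence of age change: it is kept with p
#' recorded NA.
#'
#' @param stats tibble from [gene_stats()] (carries `cor_p`).
#' @param n_tissues integer vector (recycled): per-gene n for the fractional
#'   threshold, >= 1.
#' @param alpha base significance level.
#' @return tibble: gene_id, cor_coef, cor_p, threshold, keep.
#' @export
filter_age_correlation <- function(stats, n_tissues = 1L, alpha = 0.05) {
  if (any(n_tissues < 1L, na.rm = TRUE)) abort("n_tissues must be >= 1")
  thr <- alpha / n_tissues
  tibble(
    gene_id = stats$gene_id,
    cor_coef = stats$cor_coef,
    cor_p = stats$cor_p,
    threshold = thr,
    keep = is.na(stats$cor_p) | stats$cor_p > thr
  )
}

#' Probability of discarding a truly invariant gene somewhere across tissues
#'
#' With an uncorrected per-tissue level `alpha`, a gene tested independently
#' in `n` tissues is erroneously discarded in at least one of them with
#' probability `1 - (1 - alpha)^n` (58% at alpha 0.05 and n = 17) — the
#' family-wise error motivating the fractional `alpha / n` threshold.
#'
#' @param alpha per-tissue significance level in (0, 1); 0 allowed as the
#'   degenerate no-test limit.
#' @param n_tissues number of tissues (>= 1), vectorized.
#' @return probability in `[0, 1]`.
#' @export
#' @examples
#' familywise_discard_probability(0.05, 17) # ~0.58
familywise_discard_probability <- function(alpha, n_tissues) {
  if (any(alpha < 0 | alpha >= 1)) abort("alpha must be in [0, 1)")
  if (any(n_tissues < 1)) abort("n_tissues must be >= 1")
  1 - (1 - alpha)^n_tissues
}

# Run steps 1-4 (optionally 5-6) for one tissue under one normalization.
# Returns the raw per-step flags and the statistics table.
steps_one_norm <- function(log2_tbl, ages, ctx) {
  stats <- gene_stats(log2_tbl, ages, method = ctx$correlation_method)
  if (ctx$cv_scale == "linear") {
    m <- 2^as_gene_matrix(log2_tbl)
    mu <- rowMeans(m); sdv <- row_sds(m)
    stats$cv_pct <- ifelse(!is.na(stats$mean_log2) & mu > 0, sdv / mu * 100, NA_real_)
  }
  bg <- background_mean(log2_tbl, ctx$background)
  list(
    stats = stats,
    background = bg,
    f1 = unname(filter_continuous(log2_tbl)),
    f2 = unname(filter_low_variance(stats, ctx$sd_max)),
    f3 = unname(filter_no_outliers(log2_tbl, ctx$outlier_delta)),
    f4 = unname(filter_expression_level(stats, bg)),
    f5 = unname(filter_cv(stats, ctx$cv_max_pct))
  )
}

#' Run the sequential screen (steps 1-6) over every tissue
#'
#' For each tissue the counts are normalized by TPM and TMM independently,
#' log2-transformed (zeros -> NA), and steps 1-6 applied sequentially; a gene
#' survives a step only if it passes under both normalizations. The
#' fractional threshold of the age screen uses, per gene, the number of
#' tissues in which that gene survived steps 1-4.
#'
#' @param counts tibble: `gene_id` + one column per sample (all tissues).
#' @param metadata tibble with sample_id, tissue, age_months for every
#'   sample column.
#' @param annotation gene annotation with `length_bp` (for TPM).
#' @param context a [filter_context()].
#' @return object of class `rg_pipeline`: a list with tibbles `stats`
#'   (per gene x tissue x normalization), `flags` (raw per-step flags per
#'   normalization), `filters` (cumulative both-normalization survivor flags
#'   f1-f6, `first_failed`, `final`), `survivor_counts`, `n_tissues`
#'   (per-gene n after step 4 and step 6), and the `context`.
#' @export
run_filter_pipeline <- function(counts, metadata, annotation,
                                context = filter_context()) {
  m <- as_gene_matrix(counts)
  missing <- setdiff(colnames(m), metadata$sample_id)
  if (length(missing)) {
    abort(sprintf("metadata missing sample(s): %s", paste(missing, collapse = ", ")))
  }
  meta <- metadata[match(colnames(m), metadata$sample_id), ]
  tissues <- sort(unique(meta$tissue))
  genes <- rownames(m)

  per_tissue <- lapply(tissues, function(tis) {
    cols <- which(meta$tissue == tis)
    if (length(cols) < 3L) abort(sprintf("tissue '%s' has fewer than 3 samples", tis))
    sub <- matrix_to_tibble(m[, cols, drop = FALSE])
    ages <- meta$age_months[cols]
    if (stats::var(ages) == 0) {
      abort(sprintf("tissue '%s': all samples share one age; the age screen is undefined", tis))
    }
    norm <- list(
      TPM = log2_expression(tpm(sub, annotation)),
      TMM = log2_expression(tmm_cpm(sub))
    )
    lapply(norm, steps_one_norm, ages = ages, ctx = context)
  })
  names(per_tissue) <- tissues

  # cumulative both-normalization survivors through step 4
  cum4 <- lapply(per_tissue, function(tn) {
    f <- mapply(function(a, b) a & b,
                tn$TPM[c("f1", "f2", "f3", "f4", "f5")],
                tn$TMM[c("f1", "f2", "f3", "f4", "f5")], SIMPLIFY = FALSE)
    list(
      c1 = f$f1,
      c2 = f$f1 & f$f2,
      c3 = f$f1 & f$f2 & f$f3,
      c4 = f$f1 & f$f2 & f$f3 & f$f4,
      f5 = f$f5
    )
  })
  n_pass4 <- Reduce(`+`, lapply(cum4, function(x) as.integer(x$c4)))

  # step 6 per tissue with per-gene fractional threshold
  out_stats <- list(); out_flags <- list(); out_comb <- list()
  for (tis in tissues) {
    tn <- per_tissue[[tis]]
    cc <- cum4[[tis]]
    n_gene <- pmax(n_pass4, 1L)
    keep6 <- lapply(tn, function(one) {
      filter_age_correlation(one$stats, n_tissues = n_gene, alpha = context$alpha)
    })
    f6 <- keep6$TPM$keep & keep6$TMM$keep
    c5 <- cc$c4 & cc$f5
    c6 <- c5 & f6

    for (nm in c("TPM", "TMM")) {
      st <- tn[[nm]]$stats
      st$tissue <- tis
      st$normalization <- nm
      st$cor_threshold <- keep6[[nm]]$threshold
      out_stats[[paste(tis, nm)]] <- st
      out_flags[[paste(tis, nm)]] <- tibble(
        gene_id = genes, tissue = tis, normalization = nm,
        f1 = tn[[nm]]$f1, f2 = tn[[nm]]$f2, f3 = tn[[nm]]$f3,
        f4 = tn[[nm]]$f4, f5 = tn[[nm]]$f5, f6 = keep6[[nm]]$keep
      )
    }
    comb <- tibble(
      gene_id = genes, tissue = tis,
      f1 = cc$c1, f2 = cc$c2, f3 = cc$c3, f4 = cc$c4, f5 = c5, f6 = c6
    )
    fm <- as.matrix(comb[paste0("f", 1:6)])
    comb$first_failed <- apply(fm, 1L, function(x) {
      i <- which(!x)
      if (length(i)) i[1L] else NA_integer_
    })
    comb$final <- c6
    out_comb[[tis]] <- comb
  }

  filters <- bind_rows(out_comb)
  n_pass6 <- filters %>%
    group_by(.data$gene_id) %>%
    summarise(n_pass6 = sum(.data$f6), .groups = "drop")

  survivor_counts <- filters %>%
    tidyr::pivot_longer(dplyr::all_of(paste0("f", 1:6)),
                        names_to = "step", values_to = "pass") %>%
    mutate(step = as.integer(sub("f", "", .data$step))) %>%
    group_by(.data$tissue, .data$step) %>%
    summarise(n_survivors = sum(.data$pass), .groups = "drop")

  res <- list(
    stats = bind_rows(out_stats) %>%
      select("gene_id", "tissue", "normalization", dplyr::everything()),
    flags = bind_rows(out_flags),
    filters = filters,
    survivor_counts = survivor_counts,
    n_tissues = tibble(gene_id = genes, n_pass4 = n_pass4) %>%
      left_join(n_pass6, by = "gene_id"),
    tissues = tissues,
    genes = genes,
    context = context
  )
  class(res) <- "rg_pipeline"
  res
}

#' @export
print.rg_pipeline <- function(x, ...) {
  cat(sprintf(
    "<rg_pipeline> %d genes x %d tissues; final survivors per tissue:\n",
    length(x$genes), length(x$tissues)
  ))
  fin <- x$filters %>% group_by(.data$tissue) %>%
    summarise(n = sum(.data$final), .groups = "drop")
  print(as.data.frame(fin), row.names = FALSE)
  invisible(x)
}

#' Step 7: validate candidates on an independent cohort
#'
#' On the validation data, TPM only: a candidate passes in a tissue when its
#' percent CV is at or below the cutoff AND its Spearman age-correlation
#' p-value exceeds `alpha / n`, with `n` the number of tissues in which the
#' gene survived step 6 in discovery. Candidates absent from the validation
#' matrix, or with a zero-expression sample there, fail with the reason
#' recorded.
#'
#' @param pipeline an `rg_pipeline` from [run_filter_pipeline()].
#' @param counts,metadata,annotation the validation cohort (tissue names
#'   matching discovery).
#' @param context a [filter_context()]; defaults to the discovery context.
#' @return tibble: gene_id, tissue, cv_pct, cor_p, threshold, pass, reason.
#' @export
validate_candidates <- function(pipeline, counts, metadata, annotation,
                                context = pipeline$context) {
  stopifnot(inherits(pipeline, "rg_pipeline"))
  m <- as_gene_matrix(counts)
  meta <- metadata[match(colnames(m), metadata$sample_id), ]
  tissues <- intersect(pipeline$tissues, unique(meta$tissue))
  if (!length(tissues)) abort("validation cohort shares no tissue with discovery")

  n6 <- setNames(pipeline$n_tissues$n_pass6, pipeline$n_tissues$gene_id)

  out <- lapply(tissues, function(tis) {
    cands <- pipeline$filters %>%
      filter(.data$tissue == tis, .data$f6) %>%
      pull("gene_id")
    if (!length(cands)) return(NULL)
    cols <- which(meta$tissue == tis)
    sub <- matrix_to_tibble(m[, cols, drop = FALSE])
    lg <- log2_expression(tpm(sub, annotation))
    st <- gene_stats(lg, meta$age_months[cols], method = "spearman")
    st <- st[match(cands, st$gene_id), ]
    thr <- context$alpha / pmax(n6[cands], 1L)
    measured <- cands %in% rownames(m)
    has_stats <- measured & !is.na(st$cv_pct)
    pass <- has_stats & st$cv_pct <= context$cv_max_pct &
      (is.na(st$cor_p) | st$cor_p > thr)
    reason <- dplyr::case_when(
      !measured ~ "not measured",
      !has_stats ~ "zero expression in validation",
      !pass & st$cv_pct > context$cv_max_pct ~ "CV above cutoff",
      !pass ~ "age correlation in validation",
      TRUE ~ NA_character_
    )
    tibble(
      gene_id = cands, tissue = tis, cv_pct = st$cv_pct, cor_p = st$cor_p,
      threshold = unname(thr), pass = unname(pass), reason = reason
    )
  })
  bind_rows(out)
}

#' Final per-tissue gene lists
#'
#' The step-6 survivor list per tissue, intersected with the step-7
#' validation verdict for tissues present in the validation table.
#'
#' @param pipeline an `rg_pipeline`.
#' @param validation optional tibble from [validate_candidates()].
#' @return named list of character vectors, one per tissue.
#' @export
final_gene_lists <- function(pipeline, validation = NULL) {
  stopifnot(inherits(pipeline, "rg_pipeline"))
  lists <- lapply(pipeline$tissues, function(tis) {
    g <- pipeline$filters %>%
      filter(.data$tissue == tis, .data$f6) %>% pull("gene_id")
    if (!is.null(validation) && tis %in% validation$tissue) {
      ok <- validation %>%
        filter(.data$tissue == tis, .data$pass) %>% pull("gene_id")
      g <- intersect(g, ok)
    }
    g
  })
  setNames(lists, pipeline$tissues)
}

#' Pan-tissue intersection of per-tissue gene lists
#'
#' @param lists a named list of character vectors, or an `rg_pipeline`
#'   (its step-6 lists are used).
#' @param validation optional [validate_candidates()] table when `lists` is a
#'   pipeline.
#' @return character vector of genes common to every list.
#' @export
pan_tissue_intersection <- function(lists, validation = NULL) {
  if (inherits(lists, "rg_pipeline")) lists <- final_gene_lists(lists, validation)
  if (!length(lists)) abort("need at least one tissue list")
  sort(Reduce(intersect, lists))
}

#' Life-stage subset analysis (steps 1-4)
#'
#' Reruns steps 1-4 on the samples of the requested stage(s) only, per
#' tissue and under both normalizations, and reports percent-CV
#' distributions — the basis for comparing variance structure between
#' stages. A size-matched cross-stage control (a seeded random draw of equal
#' size across all stages) is available via `control_n`.
#'
#' @inheritParams run_filter_pipeline
#' @param stages character vector of stages to keep (ignored when
#'   `control_n` is given).
#' @param control_n draw this many samples per tissue across all stages
#'   instead of subsetting by stage.
#' @param seed seed for the size-matched control draw.
#' @return list with `stats` (per gene x tissue x normalization, incl.
#'   cv_pct), `filters` (cumulative f1-f4), `survivor_counts`, and
#'   `samples_used`.
#' @export
stage_subset_analysis <- function(counts, metadata, annotation, stages,
                                  context = filter_context(),
                                  control_n = NULL, seed = NULL) {
  m <- as_gene_matrix(counts)
  meta <- metadata[match(colnames(m), metadata$sample_id), ]
  if (is.null(control_n)) {
    bad <- setdiff(stages, unique(meta$stage))
    if (length(bad)) abort(sprintf("stage(s) not present: %s", paste(bad, collapse = ", ")))
    keep_sample <- meta$stage %in% stages
  } else {
    if (!is.null(seed)) set.seed(seed)
    keep_sample <- rep(FALSE, nrow(meta))
    for (tis in unique(meta$tissue)) {
      idx <- which(meta$tissue == tis)
      if (control_n > length(idx)) abort("control_n exceeds samples in a tissue")
      keep_sample[sample(idx, control_n)] <- TRUE
    }
  }
  meta <- meta[keep_sample, ]
  m <- m[, keep_sample, drop = FALSE]

  tissues <- sort(unique(meta$tissue))
  out_stats <- list(); out_comb <- list()
  for (tis in tissues) {
    cols <- which(meta$tissue == tis)
    if (length(cols) < 3L) abort(sprintf("subset for tissue '%s' has fewer than 3 samples", tis))
    sub <- matrix_to_tibble(m[, cols, drop = FALSE])
    ages <- meta$age_months[cols]
    res <- lapply(
      list(TPM = log2_expression(tpm(sub, annotation)),
           TMM = log2_expression(tmm_cpm(sub))),
      steps_one_norm, ages = ages, ctx = context
    )
    for (nm in names(res)) {
      st <- res[[nm]]$stats
      st$tissue <- tis; st$normalization <- nm
      out_stats[[paste(tis, nm)]] <- st
    }
    f <- mapply(function(a, b) a & b,
                res$TPM[c("f1", "f2", "f3", "f4")],
                res$TMM[c("f1", "f2", "f3", "f4")], SIMPLIFY = FALSE)
    out_comb[[tis]] <- tibble(
      gene_id = rownames(m), tissue = tis,
      f1 = f$f1, f2 = f$f1 & f$f2, f3 = f$f1 & f$f2 & f$f3,
      f4 = f$f1 & f$f2 & f$f3 & f$f4
    )
  }
  filters <- bind_rows(out_comb)
  survivor_counts <- filters %>%
    tidyr::pivot_longer(dplyr::all_of(paste0("f", 1:4)),
                        names_to = "step", values_to = "pass") %>%
    mutate(step = as.integer(sub("f", "", .data$step))) %>%
    group_by(.data$tissue, .data$step) %>%
    summarise(n_survivors = sum(.data$pass), .groups = "drop")
  list(
    stats = bind_rows(out_stats),
    filters = filters,
    survivor_counts = survivor_counts,
    samples_used = meta$sample_id
  )
}

#' Classify a list of classical reference genes per tissue
#'
#' A gene is `valid` in a tissue when it appears in that tissue's final
#' list, `invalid` when it was screened but removed (the first failed step
#' is recorded), and `not assessable` when it is absent from the count
#' table.
#'
#' @param genes character vector of classical reference gene ids.
#' @param pipeline an `rg_pipeline`.
#' @param validation optional [validate_candidates()] table.
#' @return tibble: gene_id, tissue, status, failed_at, cv_pct (TPM),
#'   cor_coef (TPM).
#' @export
classify_reference_genes <- function(genes, pipeline, validation = NULL) {
  stopifnot(inherits(pipeline, "rg_pipeline"))
  if (!length(genes)) {
    return(tibble(gene_id = character(), tissue = character(),
                  status = character(), failed_at = integer(),
                  cv_pct = numeric(), cor_coef = numeric()))
  }
  finals <- final_gene_lists(pipeline, validation)
  grid <- tidyr::expand_grid(gene_id = genes, tissue = pipeline$tissues)
  tpm_stats <- pipeline$stats %>%
    filter(.data$normalization == "TPM") %>%
    select("gene_id", "tissue", "cv_pct", "cor_coef")
  grid %>%
    left_join(pipeline$filters %>% select("gene_id", "tissue", "first_failed"),
              by = c("gene_id", "tissue")) %>%
    left_join(tpm_stats, by = c("gene_id", "tissue")) %>%
    mutate(
      status = dplyr::case_when(
        !(gene_id %in% pipeline$genes) ~ "not assessable",
        purrr::map2_lgl(gene_id, tissue, ~ .x %in% finals[[.y]]) ~ "valid",
        TRUE ~ "invalid"
      ),
      failed_at = ifelse(.data$status == "invalid", .data$first_failed, NA_integer_)
    ) %>%
    select("gene_id", "tissue", "status", "failed_at", "cv_pct", "cor_coef")
}
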