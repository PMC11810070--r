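# Dual normalization (TPM, TMM-scaled CPM) and sample-level QC.

#' Transcripts-per-million normalization
#'
#' Per sample, each gene's count is divided by its exon-union length to give a
#' length-normalized rate; rates are rescaled to sum to one million, so TPM
#' approximates relative molar RNA concentration.
#'
#' @param counts tibble: `gene_id` + one numeric column per sample.
#' @param annotation tibble with `gene_id` and `length_bp` (positive, bp).
#' @param zero_sample how to treat an all-zero sample: `"error"` (default) or
#'   `"na"` (column of NA).
#' @return tibble shaped like `counts` with attribute `norm_method = "TPM"`;
#'   every column sums to 1e6.
#' @export
#' @examples
#' counts <- tibble::tibble(gene_id = c("a", "b"), s1 = c(10, 10))
#' ann <- tibble::tibble(gene_id = c("a", "b"), length_bp = c(1000, 2000))
#' tpm(counts, ann)
tpm <- function(counts, annotation, zero_sample = c("error", "na")) {
  zero_sample <- match.arg(zero_sample)
  m <- as_gene_matrix(counts)
  if (any(m < 0)) abort("counts must be non-negative")
  len <- annotation$length_bp[match(rownames(m), annotation$gene_id)]
  missing <- rownames(m)[is.na(len) | len <= 0]
  if (length(missing)) {
    abort(sprintf(
      "missing or non-positive length for gene(s): %s",
      paste(head(missing, 5L), collapse = ", ")
    ))
  }
  rate <- m / len
  totals <- colSums(rate)
  if (any(totals == 0)) {
    bad <- colnames(m)[totals == 0]
    if (zero_sample == "error") {
      abort(sprintf("all-zero sample(s): %s", paste(bad, collapse = ", ")))
    }
    totals[totals == 0] <- NA_real_
  }
  out <- sweep(rate, 2L, totals, "/") * 1e6
  res <- matrix_to_tibble(out)
  attr(res, "norm_method") <- "TPM"
  res
}

#' Trimmed-mean-of-M-values (TMM) scaling factors
#'
#' Implements the published TMM definition: the reference sample is the one
#' whose 75th-percentile relative abundance is closest to the mean across
#' samples; for every other sample, gene-wise log2 abundance ratios (M) and
#' average log2 abundances (A) are computed over genes nonzero in both, the
#' top and bottom `logratio_trim` of M and `sum_trim` of A are discarded, and
#' the factor is 2 to the precision-weighted mean of the surviving M values
#' (weights from the binomial delta-method variance). Factors are rescaled so
#' their geometric mean is 1.
#'
#' @param counts tibble: `gene_id` + one numeric column per sample (>= 2).
#' @param logratio_trim fraction of M values trimmed from each tail.
#' @param sum_trim fraction of A values trimmed from each tail.
#' @param do_weighting use delta-method precision weights (default TRUE).
#' @param ref_column optional index/name of the reference sample.
#' @return named numeric vector of per-sample scaling factors.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, sum_trim = 0.05,
                        do_weighting = TRUE, ref_column = NULL) {
  m <- as_gene_matrix(counts)
  if (ncol(m) < 2L) abort("TMM needs at least 2 samples")
  lib_size <- colSums(m)
  if (any(lib_size <= 0)) abort("every sample must have a positive total count")
  keep <- rowSums(m > 0) > 0L
  x <- m[keep, , drop = FALSE]

  if (is.null(ref_column)) {
    q75 <- apply(x, 2L, quantile, probs = 0.75) / lib_size
    ref_column <- if (median(q75) < 1e-20) {
      which.max(colSums(sqrt(x)))
    } else {
      which.min(abs(q75 - mean(q75)))
    }
  } else if (is.character(ref_column)) {
    ref_column <- match(ref_column, colnames(x))
  }

  ref <- x[, ref_column]
  n_ref <- lib_size[ref_column]
  f <- vapply(seq_len(ncol(x)), function(i) {
    obs <- x[, i]
    n_obs <- lib_size[i]
    log_r <- log2((obs / n_obs) / (ref / n_ref))
    abs_e <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
    v <- (n_obs - obs) / n_obs / obs + (n_ref - ref) / n_ref / ref
    fin <- is.finite(log_r) & is.finite(abs_e)
    log_r <- log_r[fin]; abs_e <- abs_e[fin]; v <- v[fin]
    if (!length(log_r)) {
      abort(sprintf("sample '%s' shares no nonzero genes with the reference",
                    colnames(x)[i]))
    }
    if (max(abs(log_r)) < 1e-6) return(1)
    n <- length(log_r)
    lo_l <- floor(n * logratio_trim) + 1
    hi_l <- n + 1 - lo_l
    lo_s <- floor(n * sum_trim) + 1
    hi_s <- n + 1 - lo_s
    keep_g <- (rank(log_r) >= lo_l & rank(log_r) <= hi_l) &
      (rank(abs_e) >= lo_s & rank(abs_e) <= hi_s)
    fk <- if (do_weighting) {
      sum(log_r[keep_g] / v[keep_g], na.rm = TRUE) /
        sum(1 / v[keep_g], na.rm = TRUE)
    } else {
      mean(log_r[keep_g], na.rm = TRUE)
    }
    if (is.na(fk)) fk <- 0
    2^fk
  }, numeric(1))

  f <- f / exp(mean(log(f)))
  setNames(f, colnames(m))
}

#' TMM-scaled counts per million
#'
#' Counts per million computed on effective library sizes (raw library size
#' times the TMM factor from [tmm_factors()]).
#'
#' @inheritParams tmm_factors
#' @param ... passed to [tmm_factors()].
#' @return tibble shaped like `counts` with attribute `norm_method = "TMM"`.
#' @export
tmm_cpm <- function(counts, ...) {
  m <- as_gene_matrix(counts)
  f <- tmm_factors(counts, ...)
  out <- sweep(m, 2L, colSums(m) * f, "/") * 1e6
  res <- matrix_to_tibble(out)
  attr(res, "norm_method") <- "TMM"
  res
}

#' Normalize a count table by one or both methods
#'
#' @inheritParams tpm
#' @param method `"TPM"`, `"TMM"` or `"both"`.
#' @return a single normalized tibble, or for `"both"` a named list with
#'   elements `TPM` and `TMM`.
#' @export
normalize_counts <- function(counts, annotation, method = c("both", "TPM", "TMM")) {
  method <- match.arg(method)
  switch(method,
    TPM = tpm(counts, annotation),
    TMM = tmm_cpm(counts),
    both = list(TPM = tpm(counts, annotation), TMM = tmm_cpm(counts))
  )
}

#' Elementwise log2 of a normalized expression table
#'
#' Zeros become NA (no pseudocount): downstream per-gene statistics are
#' undefined for genes with a zero-expression sample.
#'
#' @param expr normalized expression tibble (`gene_id` + sample columns).
#' @return tibble of log2 values, NA where expression is zero.
#' @export
log2_expression <- function(expr) {
  m <- as_gene_matrix(expr)
  if (any(m < 0, na.rm = TRUE)) abort("expression values must be non-negative")
  out <- log2(m)
  out[!is.finite(out)] <- NA_real_
  res <- matrix_to_tibble(out)
  attr(res, "norm_method") <- attr(expr, "norm_method")
  res
}

#' Sample-level quality control
#'
#' Flags samples below the library-size threshold (5 million counts by
#' default, inclusive: a sample passes at exactly the threshold) and,
#' when two or more tissues are present, flags possible tissue mislabels:
#' average-linkage hierarchical clustering on 1 - Spearman correlation of
#' log2 CPM (top `n_top_genes` most-variable genes, +1 pseudocount), the tree
#' cut at k = number of tissues, and a sample flagged when the majority
#' tissue of its cluster differs from its label. Flags are advisory; no
#' sample is removed.
#'
#' @param counts tibble: `gene_id` + sample columns.
#' @param metadata tibble with `sample_id` and `tissue` for every sample.
#' @param min_library library-size threshold (counts).
#' @param n_top_genes number of most-variable genes used for clustering.
#' @return tibble: sample_id, tissue, library_size, passes_depth,
#'   cluster_label, flagged_mislabel.
#' @export
qc_samples <- function(counts, metadata, min_library = 5e6, n_top_genes = 2000L) {
  m <- as_gene_matrix(counts)
  missing <- setdiff(colnames(m), metadata$sample_id)
  if (length(missing)) {
    abort(sprintf("metadata missing sample(s): %s", paste(missing, collapse = ", ")))
  }
  meta <- metadata[match(colnames(m), metadata$sample_id), ]
  lib <- colSums(m)
  out <- tibble(
    sample_id = colnames(m),
    tissue = meta$tissue,
    library_size = unname(lib),
    passes_depth = unname(lib >= min_library),
    cluster_label = NA_character_,
    flagged_mislabel = FALSE
  )

  k <- length(unique(meta$tissue))
  if (k < 2L) return(out)
  if (ncol(m) <= k) {
    warn("fewer samples than tissues; mislabel clustering skipped")
    return(out)
  }

  cpm <- sweep(m, 2L, lib, "/") * 1e6
  lg <- log2(cpm + 1)
  vars <- row_sds(lg)^2
  top <- order(vars, decreasing = TRUE)[seq_len(min(n_top_genes, nrow(lg)))]
  d <- stats::as.dist(1 - cor(lg[top, , drop = FALSE], method = "spearman"))
  cl <- cutree(hclust(d, method = "average"), k = k)
  majority <- tapply(meta$tissue, cl, function(x) names(sort(table(x), decreasing = TRUE))[1L])
  out$cluster_label <- unname(majority[as.character(cl)])
  out$flagged_mislabel <- out$cluster_label != out$tissue
  out
}
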