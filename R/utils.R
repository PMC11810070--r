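# Internal helpers shared across modules. User-facing tables are tibbles with
# a `gene_id` first column and one column per sample; numerics happen on the
# equivalent genes-x-samples matrix.

#' Convert a wide gene-by-sample tibble to a numeric matrix
#'
#' @param tbl tibble with a `gene_id` column and one numeric column per sample.
#' @param id_col name of the identifier column.
#' @return numeric matrix, rownames = gene ids, colnames = sample ids.
#' @keywords internal
#' @noRd
as_gene_matrix <- function(tbl, id_col = "gene_id") {
  stopifnot(is.data.frame(tbl))
  if (!id_col %in% names(tbl)) {
    abort(sprintf("column '%s' is required", id_col))
  }
  ids <- as.character(tbl[[id_col]])
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(sprintf("duplicate %s: %s", id_col, paste(head(dup, 5L), collapse = ", ")))
  }
  m <- as.matrix(tbl[setdiff(names(tbl), id_col)])
  if (ncol(m) == 0L) m <- matrix(numeric(), nrow = nrow(tbl), ncol = 0L)
  if (ncol(m) > 0L && !is.numeric(m)) abort("all sample columns must be numeric")
  rownames(m) <- ids
  m
}

# inverse of as_gene_matrix
matrix_to_tibble <- function(m, id_col = "gene_id") {
  out <- as_tibble(m, .name_repair = "minimal")
  out <- tibble::add_column(out, !!id_col := rownames(m), .before = 1L)
  out
}

# row-wise sample standard deviation (n - 1), NA-propagating
row_sds <- function(m) {
  n <- ncol(m)
  if (n < 2L) return(rep(NA_real_, nrow(m)))
  mu <- rowMeans(m)
  sqrt(rowSums((m - mu)^2) / (n - 1L))
}

# Student-t two-sided p-value for a correlation coefficient at n samples.
# Matches the asymptotic p used by WGCNA::corAndPvalue.
cor_pvalue <- function(r, n) {
  p <- rep(NA_real_, length(r))
  ok <- !is.na(r) & n > 2L
  rr <- pmin(pmax(r[ok], -1), 1)
  tstat <- rr * sqrt((n - 2L) / pmax(1 - rr^2, .Machine$double.eps))
  p[ok] <- 2 * pt(-abs(tstat), df = n - 2L)
  pmin(p, 1)
}

# correlation of each matrix row against a covariate, Pearson or Spearman
row_cor <- function(m, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (method == "spearman") {
    m <- t(apply(m, 1L, rank))
    y <- rank(y)
  }
  # zero-variance rows yield an undefined correlation; that is handled
  # downstream as NA, so the sd-is-zero warning is noise here
  suppressWarnings(as.vector(cor(t(m), y)))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("'%s' must be a single number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
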