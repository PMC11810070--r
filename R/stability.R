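# RT-qPCR reference-gene stability scoring: geNorm, comparative delta-Ct,
# BestKeeper, NormFinder, and the RefFinder composite (geometric mean of the
# per-method ranks). Lower is always more stable.

# samples x genes Ct matrix from a Ct tibble
ct_matrix <- function(ct) {
  gene_cols <- setdiff(names(ct), c("sample_id", "group"))
  if (length(gene_cols) < 2L) abort("need at least 2 genes")
  m <- as.matrix(ct[gene_cols])
  if (!is.numeric(m) || any(!is.finite(m))) abort("Ct values must be finite numbers")
  rownames(m) <- ct$sample_id %||% seq_len(nrow(m))
  m
}

expand_efficiency <- function(efficiency, genes) {
  if (length(efficiency) == 1L && is.null(names(efficiency))) {
    e <- setNames(rep(efficiency, length(genes)), genes)
  } else {
    e <- efficiency[genes]
    if (any(is.na(e))) abort("efficiency must cover every gene")
  }
  if (any(e <= 1)) abort("amplification efficiencies must exceed 1")
  e
}

#' geNorm expression stability measure M
#'
#' Relative quantities `Q = E^(minCt - Ct)` per gene; for each gene pair the
#' pairwise variation is the SD over samples of `log2(Q_j / Q_k)`, and a
#' gene's M is the mean of its pairwise variations against all other genes.
#' With perfect doubling (E = 2) this is a dispersion of per-sample Ct
#' differences.
#'
#' @param ct Ct tibble: `sample_id`, `group`, one numeric column per gene.
#' @param efficiency scalar or per-gene named vector of amplification
#'   efficiencies (default 2, perfect doubling).
#' @return tibble: gene_id, genorm_m.
#' @export
genorm <- function(ct, efficiency = 2) {
  m <- ct_matrix(ct)
  if (nrow(m) < 2L) abort("need at least 2 samples")
  e <- expand_efficiency(efficiency, colnames(m))
  # log2 Q, one column per gene
  lq <- sweep(-m, 2L, apply(m, 2L, min), `+`)
  lq <- sweep(lq, 2L, log2(e), `*`)
  k <- ncol(lq)
  mm <- numeric(k)
  for (j in seq_len(k)) {
    v <- vapply(seq_len(k)[-j], function(kk) sd(lq[, j] - lq[, kk]), numeric(1))
    mm[j] <- mean(v)
  }
  tibble(gene_id = colnames(m), genorm_m = mm)
}

#' Comparative delta-Ct stability score
#'
#' For every gene pair the per-sample Ct difference is formed; a gene's
#' score is the mean over partner genes of the SD of those differences.
#'
#' @inheritParams genorm
#' @return tibble: gene_id, deltact_mean_sd.
#' @export
delta_ct <- function(ct) {
  m <- ct_matrix(ct)
  if (nrow(m) < 2L) abort("need at least 2 samples")
  k <- ncol(m)
  score <- numeric(k)
  for (j in seq_len(k)) {
    v <- vapply(seq_len(k)[-j], function(kk) sd(m[, j] - m[, kk]), numeric(1))
    score[j] <- mean(v)
  }
  tibble(gene_id = colnames(m), deltact_mean_sd = score)
}

#' BestKeeper descriptive stability statistics
#'
#' Per-gene SD and percent CV of the raw Ct values, plus the Pearson
#' correlation of each gene's Ct with the BestKeeper index (the per-sample
#' geometric mean of Ct across genes).
#'
#' @inheritParams genorm
#' @return tibble: gene_id, bestkeeper_sd, bestkeeper_cv, bestkeeper_r,
#'   bestkeeper_p.
#' @export
bestkeeper <- function(ct) {
  m <- ct_matrix(ct)
  if (nrow(m) < 2L) abort("need at least 2 samples")
  if (any(m <= 0)) abort("Ct values must be positive for the geometric-mean index")
  sdv <- apply(m, 2L, sd)
  mu <- colMeans(m)
  index <- exp(rowMeans(log(m)))
  if (sd(index) == 0) {
    r <- rep(NA_real_, ncol(m))
    p <- rep(NA_real_, ncol(m))
  } else {
    r <- as.vector(cor(m, index))
    r[sdv == 0] <- NA_real_
    p <- cor_pvalue(r, nrow(m))
  }
  tibble(
    gene_id = colnames(m), bestkeeper_sd = unname(sdv),
    bestkeeper_cv = unname(sdv / mu * 100),
    bestkeeper_r = r, bestkeeper_p = p
  )
}

#' NormFinder model-based stability value
#'
#' Implements the variance-decomposition approach of the NormFinder
#' algorithm on log-scale relative quantities (`log2 Q = -Ct * log2 E`).
#' Sample effects are removed by centering each sample across genes; per
#' gene and group the intra-group variance is estimated with the
#' gene-number bias correction and floored at zero, and the inter-group
#' bias (the gene x group interaction, centered across groups) is shrunk
#' toward zero by its sampling variance. The stability value is the mean
#' over groups of |shrunken bias| + the shrunken bias' posterior SD; with a
#' single group it reduces to the intra-group SD.
#'
#' @inheritParams genorm
#' @param group name of the grouping column in `ct` (default `"group"`).
#' @return tibble: gene_id, normfinder_stability, intergroup_bias (mean
#'   |shrunken bias|), intragroup_sd (root mean intra-group variance).
#' @export
normfinder <- function(ct, group = "group", efficiency = 2) {
  m <- ct_matrix(ct)
  if (!group %in% names(ct)) abort(sprintf("grouping column '%s' not found", group))
  grp <- as.character(ct[[group]])
  e <- expand_efficiency(efficiency, colnames(m))
  y <- sweep(-m, 2L, log2(e), `*`) # log2 relative quantity
  k <- ncol(y)
  groups <- unique(grp)
  G <- length(groups)
  if (G >= 2L && any(table(grp) < 2L)) {
    abort("every group needs at least 2 samples")
  }

  # remove sample effects
  z <- y - rowMeans(y)

  d <- matrix(0, nrow = k, ncol = G, dimnames = list(colnames(m), groups))
  s2 <- matrix(0, nrow = k, ncol = G)
  n_g <- integer(G)
  for (gi in seq_along(groups)) {
    rows <- grp == groups[gi]
    n_g[gi] <- sum(rows)
    zg <- z[rows, , drop = FALSE]
    d[, gi] <- colMeans(zg)
    s2[, gi] <- apply(zg, 2L, stats::var)
  }

  # intra-group variance with the k-gene bias correction (centering across
  # genes couples the residuals); fall back to the raw variance when k = 2
  sigma2 <- if (k > 2L) {
    sbar <- colMeans(s2)
    pmax(sweep(s2, 2L, sbar / (k - 1L), `-`) * k / (k - 2L), 0)
  } else {
    s2
  }

  if (G == 1L) {
    stab <- unname(sqrt(sigma2[, 1L]))
    return(tibble(
      gene_id = colnames(m), normfinder_stability = stab,
      intergroup_bias = 0, intragroup_sd = stab
    ))
  }

  d <- d - rowMeans(d) # gene x group interaction, centered across groups
  vard <- sweep(sigma2, 2L, n_g, `/`) # sampling variance of d
  gamma2 <- max(0, sum(d^2) / ((k - 1L) * (G - 1L)) - mean(vard))
  if (gamma2 > 0) {
    shrink <- gamma2 / (gamma2 + vard)
    d_tilde <- d * shrink
    var_tilde <- vard * shrink
  } else {
    d_tilde <- d * 0
    var_tilde <- vard * 0
  }
  rho <- abs(d_tilde) + sqrt(var_tilde)
  tibble(
    gene_id = colnames(m),
    normfinder_stability = unname(rowMeans(rho)),
    intergroup_bias = unname(rowMeans(abs(d_tilde))),
    intragroup_sd = unname(sqrt(rowMeans(sigma2)))
  )
}

#' RefFinder composite score
#'
#' Within each method genes are ranked ascending by instability (1 = most
#' stable; geNorm by M, NormFinder by stability value, BestKeeper by Ct SD,
#' delta-Ct by mean SD), ties receiving average ranks; the composite is the
#' geometric mean of the per-method ranks over the methods available for
#' that gene.
#'
#' @param scores tibble with `gene_id` and any of the columns `genorm_m`,
#'   `normfinder_stability`, `bestkeeper_sd`, `deltact_mean_sd`.
#' @return `scores` with per-method rank columns, `n_methods`, and
#'   `reffinder_score` (in `[1, n_genes]`).
#' @export
reffinder <- function(scores) {
  methods <- intersect(
    c("genorm_m", "normfinder_stability", "bestkeeper_sd", "deltact_mean_sd"),
    names(scores)
  )
  if (length(methods) < 2L) abort("need scores from at least 2 methods")
  if (nrow(scores) < 2L) abort("need at least 2 genes")
  ranks <- lapply(methods, function(mm) {
    v <- scores[[mm]]
    r <- rep(NA_real_, length(v))
    r[!is.na(v)] <- rank(v[!is.na(v)], ties.method = "average")
    r
  })
  rk <- do.call(cbind, ranks)
  colnames(rk) <- paste0("rank_", sub("_(m|mean_sd|stability|sd)$", "", methods))
  n_methods <- rowSums(!is.na(rk))
  if (any(n_methods < 1L)) abort("a gene has no method score at all")
  comp <- exp(rowMeans(log(rk), na.rm = TRUE))
  out <- dplyr::bind_cols(scores, as_tibble(rk))
  out$n_methods <- as.integer(n_methods)
  out$reffinder_score <- comp
  out
}

#' Score a Ct table with all stability methods and the RefFinder composite
#'
#' @inheritParams normfinder
#' @return tibble of class `rg_stability`: all per-method scores, per-method
#'   ranks and the RefFinder composite, sorted most stable first.
#' @export
#' @examples
#' sim <- simulate_ct_table(seed = 3)
#' rank_stability(sim$ct)
rank_stability <- function(ct, group = "group", efficiency = 2) {
  out <- genorm(ct, efficiency) %>%
    left_join(delta_ct(ct), by = "gene_id") %>%
    left_join(bestkeeper(ct), by = "gene_id") %>%
    left_join(normfinder(ct, group = group, efficiency = efficiency), by = "gene_id") %>%
    reffinder() %>%
    arrange(.data$reffinder_score)
  class(out) <- c("rg_stability", class(out))
  out
}
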