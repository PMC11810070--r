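# Shared fixtures and independent oracles for the test suite.

# small but fully structured cohort: 2 tissues, 120 genes, 40 samples/tissue
small_config <- function(seed = 1L, ...) {
  cohort_config(
    n_tissues = 2L,
    genes_per_class = c(
      stable_high = 30L, stable_low = 20L, age_trend = 20L,
      high_var = 15L, dropout = 15L, outlier_spiked = 10L,
      young_variable = 10L
    ),
    samples_per_age_per_sex = 2L,
    seed = seed,
    ...
  )
}

# wide tibble from a plain matrix with default dimnames
wide_counts <- function(m, genes = NULL, samples = NULL) {
  genes <- genes %||% sprintf("g%03d", seq_len(nrow(m)))
  samples <- samples %||% sprintf("s%02d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  tibble::add_column(out, gene_id = genes, .before = 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive-enumeration oracle for the family-wise discard probability:
# sum the probability of every outcome of n independent Bernoulli(alpha)
# discard events that contains at least one discard
familywise_bruteforce <- function(alpha, n) {
  outcomes <- expand.grid(rep(list(c(0L, 1L)), n))
  p <- apply(outcomes, 1L, function(o) prod(ifelse(o == 1L, alpha, 1 - alpha)))
  sum(p[rowSums(outcomes) > 0L])
}

# exhaustive hypergeometric oracle for the two-sided Fisher exact p-value
# (minimum-likelihood convention): sum over the support of all table
# probabilities not exceeding the observed one
fisher_bruteforce <- function(a, b, c, d) {
  m <- a + c
  n <- b + d
  k <- a + b
  x <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(x, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# literal sample standard deviation for hand checks
sd1 <- function(x) sqrt(sum((x - mean(x))^2) / (length(x) - 1))
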