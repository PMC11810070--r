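# Synthetic multi-tissue cohort generator with planted gene classes.
#
# Counts are negative-binomial around class-specific mean curves. Per-gene
# baselines are defined on the log2 *normalized* scale; expected counts are
# proportional to 2^baseline * sqrt(L_g / L_geo) so that the per-gene length
# factor is split evenly between TPM (which divides by length) and TMM-scaled
# CPM (which does not), keeping each planted class at its intended level under
# both normalizations.

#' Default stage map: month-of-age to lifespan stage
#'
#' Adolescent (< 3 mo), young (3-6 mo), middle (9-15 mo), old (>= 18 mo).
#'
#' @param age_months numeric vector of ages in months.
#' @return character vector of stages.
#' @export
#' @examples
#' stage_of_age(c(1, 3, 12, 24))
stage_of_age <- function(age_months) {
  if (any(age_months <= 0)) abort("ages must be strictly positive")
  cut(age_months,
    breaks = c(0, 3, 9, 18, Inf), right = FALSE,
    labels = c("adolescent", "young", "middle", "old")
  ) |> as.character()
}

#' Configuration for the synthetic cohort simulator
#'
#' Defaults describe the study conditions the generator emulates: 3 tissues,
#' ~600 genes spread over 7 planted classes, a 10-point age grid spanning
#' 1 to 27 months, both sexes, 4 samples per age per sex, lognormal library
#' sizes around 10 million counts.
#'
#' Planted classes and the filter each is designed to trip:
#' \describe{
#'   \item{stable_high}{high, flat expression; survives all filters (truth
#'     positives).}
#'   \item{stable_low}{flat but below the tissue-wide mean; removed by the
#'     expression-level filter (step 4).}
#'   \item{age_trend}{log2 expression linear in age at
#'     `age_slope_range` log2/month (random sign); removed by the age
#'     correlation filter (step 6).}
#'   \item{high_var}{extra log2 noise targeting `extra_cv_pct` percent CV;
#'     removed by the variance filters (step 2 or 5).}
#'   \item{dropout}{a fraction `dropout_rate` of samples zeroed; removed by
#'     the continuous-expression filter (step 1).}
#'   \item{outlier_spiked}{one sample per tissue shifted by
#'     `outlier_magnitude` log2 units; removed at or before the outlier
#'     filter (step 3).}
#'   \item{young_variable}{extra log2 noise (`young_extra_sd`) in young-stage
#'     samples only; exercises the life-stage subset analysis.}
#' }
#'
#' @param n_tissues number of tissues.
#' @param genes_per_class named integer vector, class name -> gene count.
#' @param ages_months age grid in months (strictly positive).
#' @param samples_per_age_per_sex replicates per age per sex per tissue.
#' @param sexes subset of `c("F", "M")`.
#' @param baseline_log2_mean_range interval for mid-expressed classes
#'   (log2 normalized units).
#' @param stable_high_log2_range,stable_low_log2_range intervals for the
#'   high- and low-expressed flat classes.
#' @param dispersion negative-binomial dispersion (0 = Poisson).
#' @param library_size_log_mean,library_size_log_sd lognormal parameters for
#'   per-sample total counts.
#' @param age_slope_range interval of |slope| for the age-trending class
#'   (log2 units per month); sign randomized per gene.
#' @param extra_cv_pct target percent CV (log2 scale) for the high-variance
#'   class.
#' @param dropout_rate fraction of samples zeroed for the dropout class.
#' @param outlier_magnitude log2 offset injected for the spiked class
#'   (must exceed 2, the outlier filter cutoff).
#' @param young_extra_sd extra log2 SD applied in the young stage only for
#'   the `young_variable` class.
#' @param sex_effect_log2,sex_effect_fraction optional constant log2 offset
#'   for males applied to a random gene fraction (default off).
#' @param cgi_prob_by_class named numeric vector, class -> probability the
#'   promoter carries a CpG island; unnamed classes use the `default` entry.
#' @param gene_length_range exon-union length interval, log-uniform (bp).
#' @param seed integer seed; every draw is reproducible from it.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_tissues = 3L,
                          genes_per_class = c(
                            stable_high = 100L, stable_low = 100L,
                            age_trend = 100L, high_var = 100L,
                            dropout = 80L, outlier_spiked = 60L,
                            young_variable = 60L
                          ),
                          ages_months = c(1, 3, 6, 9, 12, 15, 18, 21, 24, 27),
                          samples_per_age_per_sex = 4L,
                          sexes = c("F", "M"),
                          baseline_log2_mean_range = c(6, 8),
                          stable_high_log2_range = c(9, 11),
                          stable_low_log2_range = c(3, 4),
                          dispersion = 0.05,
                          library_size_log_mean = log(1e7),
                          library_size_log_sd = 0.15,
                          age_slope_range = c(0.05, 0.1),
                          extra_cv_pct = 35,
                          dropout_rate = 0.2,
                          outlier_magnitude = 4,
                          young_extra_sd = 1,
                          sex_effect_log2 = 0,
                          sex_effect_fraction = 0,
                          cgi_prob_by_class = c(stable_high = 0.9, default = 0.5),
                          gene_length_range = c(500, 1e5),
                          seed = 1L) {
  cfg <- list(
    n_tissues = as.integer(n_tissues),
    genes_per_class = genes_per_class,
    ages_months = ages_months,
    samples_per_age_per_sex = as.integer(samples_per_age_per_sex),
    sexes = sexes,
    baseline_log2_mean_range = baseline_log2_mean_range,
    stable_high_log2_range = stable_high_log2_range,
    stable_low_log2_range = stable_low_log2_range,
    dispersion = dispersion,
    library_size_log_mean = library_size_log_mean,
    library_size_log_sd = library_size_log_sd,
    age_slope_range = age_slope_range,
    extra_cv_pct = extra_cv_pct,
    dropout_rate = dropout_rate,
    outlier_magnitude = outlier_magnitude,
    young_extra_sd = young_extra_sd,
    sex_effect_log2 = sex_effect_log2,
    sex_effect_fraction = sex_effect_fraction,
    cgi_prob_by_class = cgi_prob_by_class,
    gene_length_range = gene_length_range,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (length(cfg$genes_per_class) == 0L || sum(cfg$genes_per_class) == 0L) {
    abort("genes_per_class must name at least one class with > 0 genes")
  }
  if (any(cfg$genes_per_class < 0L)) abort("gene class counts must be non-negative")
  if (cfg$n_tissues < 1L) abort("need at least one tissue")
  if (cfg$samples_per_age_per_sex < 1L) abort("need at least one sample per age per sex")
  if (any(cfg$ages_months <= 0)) abort("ages must be strictly positive")
  if (!all(cfg$sexes %in% c("F", "M")) || length(cfg$sexes) < 1L) {
    abort("sexes must be a non-empty subset of {F, M}")
  }
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1) abort("dropout_rate must be in [0, 1)")
  if (cfg$outlier_magnitude <= 2) {
    abort("outlier_magnitude must exceed 2 (the outlier filter cutoff)")
  }
  if (cfg$dispersion < 0) abort("dispersion must be non-negative")
  if (cfg$young_extra_sd < 0 || cfg$extra_cv_pct < 0) abort("noise parameters must be non-negative")
  invisible(cfg)
}

gene_classes <- c(
  "stable_high", "stable_low", "age_trend", "high_var",
  "dropout", "outlier_spiked", "young_variable"
)

# draw negative-binomial (Poisson when dispersion == 0) counts around mu
draw_counts <- function(mu, dispersion) {
  if (dispersion > 0) {
    rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  } else {
    rpois(length(mu), lambda = mu)
  }
}

#' Simulate a multi-tissue, age-structured RNA-seq cohort
#'
#' Generates one combined count table over all tissues, sample metadata,
#' gene annotation (exon-union length, GC, promoter CpG-island status,
#' transcript-length summaries) and the planted-truth table recording each
#' gene's class and realized parameters. Bit-identical under a fixed seed.
#'
#' @param config a [cohort_config()].
#' @return a list with tibbles `counts` (gene_id + one column per sample),
#'   `metadata`, `annotation`, and `truth`.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(
#'   n_tissues = 1, genes_per_class = c(stable_high = 5, dropout = 3),
#'   ages_months = c(3, 27), samples_per_age_per_sex = 2, seed = 7
#' ))
#' dim(cohort$counts)
simulate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  set.seed(config$seed)

  classes <- rep(names(config$genes_per_class), times = config$genes_per_class)
  n_genes <- length(classes)
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))

  base_range <- function(cl) {
    switch(cl,
      stable_high = config$stable_high_log2_range,
      stable_low = config$stable_low_log2_range,
      config$baseline_log2_mean_range
    )
  }
  baseline <- vapply(classes, function(cl) {
    r <- base_range(cl)
    runif(1L, r[1L], r[2L])
  }, numeric(1))

  slope <- numeric(n_genes)
  trend <- classes == "age_trend"
  slope[trend] <- runif(sum(trend), config$age_slope_range[1L], config$age_slope_range[2L]) *
    sample(c(-1, 1), sum(trend), replace = TRUE)

  extra_sd <- numeric(n_genes)
  hv <- classes == "high_var"
  extra_sd[hv] <- config$extra_cv_pct / 100 * baseline[hv]

  sexed <- rbinom(n_genes, 1L, config$sex_effect_fraction) == 1L

  # annotation ------------------------------------------------------------
  lr <- log(config$gene_length_range)
  length_bp <- round(exp(runif(n_genes, lr[1L], lr[2L])))
  cgi_p <- config$cgi_prob_by_class[classes]
  cgi_p[is.na(cgi_p)] <- config$cgi_prob_by_class[["default"]] %||% 0.5
  cgi <- ifelse(rbinom(n_genes, 1L, cgi_p) == 1L, "CGI+", "CGI-")
  tl_median <- pmax(200L, round(length_bp * runif(n_genes, 0.6, 0.95)))
  tl_min <- pmax(100L, round(tl_median * runif(n_genes, 0.4, 1)))
  tl_max <- round(tl_median * runif(n_genes, 1, 1.5))
  annotation <- tibble(
    gene_id = gene_ids,
    length_bp = as.integer(length_bp),
    gc_fraction = runif(n_genes, 0.35, 0.65),
    cgi_status = cgi,
    transcript_length_median = as.integer(tl_median),
    transcript_length_min = as.integer(pmin(tl_min, tl_median)),
    transcript_length_max = as.integer(pmax(tl_max, tl_median)),
    transcript_length_canonical = as.integer(tl_median)
  )

  # samples ---------------------------------------------------------------
  design <- expand.grid(
    rep = seq_len(config$samples_per_age_per_sex),
    sex = config$sexes,
    age_months = config$ages_months,
    tissue = sprintf("tissue%02d", seq_len(config$n_tissues)),
    stringsAsFactors = FALSE
  )
  metadata <- tibble(
    sample_id = sprintf(
      "%s_a%02g_%s_r%d", design$tissue, design$age_months, design$sex, design$rep
    ),
    tissue = design$tissue,
    age_months = design$age_months,
    sex = design$sex,
    stage = stage_of_age(design$age_months)
  )

  age_center <- mean(config$ages_months)
  len_factor <- sqrt(length_bp / exp(mean(log(length_bp))))

  counts <- matrix(0, nrow = n_genes, ncol = nrow(metadata),
                   dimnames = list(gene_ids, metadata$sample_id))
  for (j in seq_len(nrow(metadata))) {
    r <- baseline + slope * (metadata$age_months[j] - age_center)
    if (metadata$sex[j] == "M" && config$sex_effect_log2 != 0) {
      r <- r + ifelse(sexed, config$sex_effect_log2, 0)
    }
    # planted over-dispersion, bounded at 2.5 SD so a single tail draw
    # cannot swallow a whole library and distort every other gene's share
    noise <- rnorm(n_genes, 0, extra_sd)
    r <- r + pmin(pmax(noise, -2.5 * extra_sd), 2.5 * extra_sd)
    if (metadata$stage[j] == "young" && config$young_extra_sd > 0) {
      yv <- classes == "young_variable"
      ynoise <- rnorm(sum(yv), 0, config$young_extra_sd)
      r[yv] <- r[yv] + pmin(pmax(ynoise, -2.5 * config$young_extra_sd),
                            2.5 * config$young_extra_sd)
    }
    w <- 2^r * len_factor
    total <- rlnorm(1L, config$library_size_log_mean, config$library_size_log_sd)
    counts[, j] <- draw_counts(total * w / sum(w), config$dispersion)
  }

  # planted perturbations applied per tissue ------------------------------
  for (tis in unique(metadata$tissue)) {
    cols <- which(metadata$tissue == tis)
    drop_genes <- which(classes == "dropout")
    if (length(drop_genes) && config$dropout_rate > 0) {
      mask <- matrix(
        rbinom(length(drop_genes) * length(cols), 1L, config$dropout_rate),
        nrow = length(drop_genes)
      )
      counts[drop_genes, cols][mask == 1L] <- 0
    }
    spike_genes <- which(classes == "outlier_spiked")
    for (g in spike_genes) {
      jcol <- cols[sample.int(length(cols), 1L)]
      counts[g, jcol] <- round(counts[g, jcol] * 2^config$outlier_magnitude)
    }
  }

  truth <- tibble(
    gene_id = gene_ids,
    class_label = classes,
    baseline_log2 = unname(baseline),
    age_slope = slope,
    extra_sd_log2 = extra_sd,
    cgi_status = cgi,
    sex_affected = sexed
  )

  list(
    counts = matrix_to_tibble(counts),
    metadata = metadata,
    annotation = annotation,
    truth = truth
  )
}

#' Simulate an RT-qPCR Ct table with stable and unstable genes
#'
#' Ct values are Gaussian around per-gene baselines. Stable genes have no
#' group effect and SD `stable_sd`; unstable genes get group-dependent shifts
#' spanning `group_shift` cycles and SD `unstable_sd`.
#'
#' @param n_genes total genes (>= 2); the first `n_stable` are stable.
#' @param n_stable number of stable genes (default half).
#' @param groups character vector of group labels (e.g. age x sex cells).
#' @param reps replicates per group (>= 2).
#' @param stable_sd,unstable_sd Ct noise SD per class (>= 0).
#' @param group_shift total spread of group-dependent Ct shifts for unstable
#'   genes (Ct units).
#' @param baseline_ct_range interval for per-gene baseline Ct.
#' @param seed integer seed.
#' @return list with `ct` (tibble: sample_id, group, one column per gene) and
#'   `truth` (gene_id, class_label, baseline_ct).
#' @export
simulate_ct_table <- function(n_genes = 8L,
                              n_stable = ceiling(n_genes / 2),
                              groups = c("young_F", "young_M", "old_F", "old_M"),
                              reps = 3L,
                              stable_sd = 0.1,
                              unstable_sd = 1,
                              group_shift = 2,
                              baseline_ct_range = c(18, 28),
                              seed = 1L) {
  if (n_genes < 2L) abort("need at least 2 genes")
  if (length(groups) < 2L) abort("need at least 2 groups")
  if (reps < 2L) abort("need at least 2 replicates per group")
  if (stable_sd < 0 || unstable_sd < 0) abort("Ct noise SDs must be non-negative")
  if (n_stable < 0L || n_stable > n_genes) abort("n_stable out of range")
  set.seed(seed)

  gene_ids <- sprintf("rg%02d", seq_len(n_genes))
  class_label <- c(rep("stable", n_stable), rep("unstable", n_genes - n_stable))
  baseline <- runif(n_genes, baseline_ct_range[1L], baseline_ct_range[2L])

  n_samples <- length(groups) * reps
  group_of <- rep(groups, each = reps)

  # unstable genes: per-gene random assignment of centered group offsets
  offsets <- matrix(0, nrow = n_genes, ncol = length(groups),
                    dimnames = list(gene_ids, groups))
  spread <- seq(-0.5, 0.5, length.out = length(groups)) * group_shift
  for (g in which(class_label == "unstable")) {
    offsets[g, ] <- sample(spread)
  }

  ct <- matrix(NA_real_, nrow = n_samples, ncol = n_genes,
               dimnames = list(NULL, gene_ids))
  for (g in seq_len(n_genes)) {
    noise_sd <- if (class_label[g] == "stable") stable_sd else unstable_sd
    ct[, g] <- baseline[g] + offsets[g, match(group_of, groups)] +
      rnorm(n_samples, 0, noise_sd)
  }

  ct_tbl <- tibble(
    sample_id = sprintf("s%02d", seq_len(n_samples)),
    group = group_of
  )
  ct_tbl <- dplyr::bind_cols(ct_tbl, as_tibble(ct))

  list(
    ct = ct_tbl,
    truth = tibble(gene_id = gene_ids, class_label = class_label,
                   baseline_ct = baseline)
  )
}
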