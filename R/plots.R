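# ggplot2 helpers for the main result types.

#' Survivor-count funnel across filter steps
#'
#' Bar chart of cumulative survivor counts per step, one panel per tissue.
#'
#' @param pipeline an `rg_pipeline`.
#' @return a ggplot object.
#' @export
plot_filter_funnel <- function(pipeline) {
  stopifnot(inherits(pipeline, "rg_pipeline"))
  ggplot2::ggplot(
    pipeline$survivor_counts,
    ggplot2::aes(x = factor(.data$step), y = .data$n_survivors)
  ) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::facet_wrap(~tissue) +
    ggplot2::labs(
      x = "filter step", y = "surviving genes",
      title = "Sequential filter survivor counts"
    ) +
    ggplot2::theme_minimal()
}

#' Percent-CV distribution by last step survived
#'
#' @param pipeline an `rg_pipeline`.
#' @param normalization which normalization's statistics to show.
#' @return a ggplot object.
#' @export
plot_cv_by_filter <- function(pipeline, normalization = "TPM") {
  stopifnot(inherits(pipeline, "rg_pipeline"))
  df <- pipeline$stats %>%
    filter(.data$normalization == .env$normalization) %>%
    left_join(
      pipeline$filters %>% select("gene_id", "tissue", "first_failed"),
      by = c("gene_id", "tissue")
    ) %>%
    mutate(
      last_step = ifelse(is.na(.data$first_failed), "final",
                         as.character(.data$first_failed - 1L))
    ) %>%
    filter(!is.na(.data$cv_pct))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$last_step, y = .data$cv_pct)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::facet_wrap(~tissue) +
    ggplot2::labs(
      x = "last step survived", y = "% CV (log2 scale)",
      title = sprintf("%%CV by filtering depth (%s)", normalization)
    ) +
    ggplot2::theme_minimal()
}

#' Plot stability scores per method with the RefFinder ordering
#'
#' @param object an `rg_stability` from [rank_stability()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot rg_stability
#' @export
autoplot.rg_stability <- function(object, ...) {
  df <- tidy(object) %>%
    mutate(gene_id = factor(.data$gene_id,
                            levels = object$gene_id[order(object$reffinder_score)]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene_id, y = .data$score)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~method, scales = "free_y") +
    ggplot2::labs(
      x = NULL, y = "instability score (lower = more stable)",
      title = "Reference-gene stability by method (RefFinder order)"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
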