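# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a filter pipeline into one row per gene, tissue and step
#'
#' @param x an `rg_pipeline`.
#' @param ... unused.
#' @return tibble: gene_id, tissue, step, pass (cumulative survivor flag).
#' @method tidy rg_pipeline
#' @export
tidy.rg_pipeline <- function(x, ...) {
  x$filters %>%
    tidyr::pivot_longer(dplyr::all_of(paste0("f", 1:6)),
                        names_to = "step", values_to = "pass") %>%
    mutate(step = as.integer(sub("f", "", .data$step))) %>%
    select("gene_id", "tissue", "step", "pass")
}

#' One-row summary of a filter pipeline
#'
#' @param x an `rg_pipeline`.
#' @param ... unused.
#' @return tibble: n_genes, n_tissues, alpha, correlation_method,
#'   n_final_min/median/max (per-tissue final list sizes), n_pan_tissue.
#' @method glance rg_pipeline
#' @export
glance.rg_pipeline <- function(x, ...) {
  finals <- x$filters %>%
    group_by(.data$tissue) %>%
    summarise(n = sum(.data$final), .groups = "drop") %>%
    pull("n")
  tibble(
    n_genes = length(x$genes),
    n_tissues = length(x$tissues),
    alpha = x$context$alpha,
    correlation_method = x$context$correlation_method,
    n_final_min = min(finals), n_final_median = median(finals),
    n_final_max = max(finals),
    n_pan_tissue = length(pan_tissue_intersection(x))
  )
}

#' Tidy a stability table into one row per gene and method
#'
#' @param x an `rg_stability` from [rank_stability()].
#' @param ... unused.
#' @return tibble: gene_id, method, score, rank.
#' @method tidy rg_stability
#' @export
tidy.rg_stability <- function(x, ...) {
  map <- c(
    genorm = "genorm_m", deltact = "deltact_mean_sd",
    bestkeeper = "bestkeeper_sd", normfinder = "normfinder_stability"
  )
  rows <- purrr::imap(map, function(col, nm) {
    tibble(
      gene_id = x$gene_id, method = nm, score = x[[col]],
      rank = x[[paste0("rank_", nm)]]
    )
  })
  bind_rows(rows) %>% arrange(.data$gene_id, .data$method)
}

#' One-row summary of a stability table
#'
#' @param x an `rg_stability`.
#' @param ... unused.
#' @return tibble: n_genes, n_methods, best_gene, best_score, worst_gene,
#'   worst_score (RefFinder composite).
#' @method glance rg_stability
#' @export
glance.rg_stability <- function(x, ...) {
  o <- order(x$reffinder_score)
  tibble(
    n_genes = nrow(x),
    n_methods = max(x$n_methods),
    best_gene = x$gene_id[o[1L]],
    best_score = x$reffinder_score[o[1L]],
    worst_gene = x$gene_id[o[length(o)]],
    worst_score = x$reffinder_score[o[length(o)]]
  )
}
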