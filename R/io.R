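# Readers/writers for the package's tabular artifacts. Plain TSV/CSV with
# required headers; a "# agestable schema_version=1" comment line is written
# first and comment lines are skipped on read. NA statistics are written as
# empty strings.

SCHEMA_VERSION <- 1L

write_with_schema <- function(tbl, path, delim) {
  readr::write_lines(sprintf("# agestable schema_version=%d", SCHEMA_VERSION), path)
  readr::write_delim(tbl, path, delim = delim, na = "", append = TRUE,
                     col_names = TRUE)
  invisible(path)
}

read_table_checked <- function(path, delim, required, numeric_cols = character(),
                               character_cols = character()) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  spec <- do.call(
    readr::cols,
    c(list(.default = readr::col_guess()),
      setNames(rep(list(readr::col_character()), length(character_cols)),
               character_cols))
  )
  tbl <- readr::read_delim(path, delim = delim, comment = "#",
                           show_col_types = FALSE, na = c("", "NA"),
                           trim_ws = TRUE, col_types = spec)
  missing <- setdiff(required, names(tbl))
  if (length(missing)) {
    abort(sprintf("%s: missing required column(s): %s",
                  basename(path), paste(missing, collapse = ", ")))
  }
  for (cc in intersect(numeric_cols, names(tbl))) {
    tbl[[cc]] <- as.numeric(tbl[[cc]])
  }
  tbl
}

#' Read a raw count table (TSV: gene_id + one column per sample)
#'
#' @param path TSV file path.
#' @return validated counts tibble.
#' @export
read_counts <- function(path) {
  tbl <- read_table_checked(path, "\t", "gene_id")
  if (ncol(tbl) < 2L) abort("count table has no sample columns")
  m <- as_gene_matrix(tbl) # checks duplicates / numeric
  bad <- which(m < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf("negative count at gene '%s', sample '%s'",
                  rownames(m)[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
  }
  tbl
}

#' Write a count or expression table to TSV
#' @param tbl counts/expression tibble.
#' @param path output path.
#' @export
write_counts <- function(tbl, path) write_with_schema(tbl, path, "\t")

#' Read sample metadata (CSV: sample_id, tissue, age_months, sex, stage)
#'
#' @param path CSV file path.
#' @param counts optional counts tibble; if given, every sample column must
#'   have exactly one metadata row.
#' @return validated metadata tibble.
#' @export
read_metadata <- function(path, counts = NULL) {
  tbl <- read_table_checked(path, ",",
                            c("sample_id", "tissue", "age_months", "sex", "stage"),
                            numeric_cols = "age_months",
                            character_cols = c("sample_id", "tissue", "sex", "stage"))
  if (anyDuplicated(tbl$sample_id)) {
    abort(sprintf("duplicate sample_id: %s",
                  tbl$sample_id[duplicated(tbl$sample_id)][1L]))
  }
  bad_sex <- setdiff(unique(tbl$sex), c("F", "M"))
  if (length(bad_sex)) abort(sprintf("unknown sex label(s): %s", paste(bad_sex, collapse = ", ")))
  bad_stage <- setdiff(unique(tbl$stage), c("adolescent", "young", "middle", "old"))
  if (length(bad_stage)) abort(sprintf("unknown stage label(s): %s", paste(bad_stage, collapse = ", ")))
  if (any(is.na(tbl$age_months) | tbl$age_months <= 0)) {
    abort(sprintf("non-positive or missing age for sample '%s'",
                  tbl$sample_id[which(is.na(tbl$age_months) | tbl$age_months <= 0)[1L]]))
  }
  if (!is.null(counts)) {
    samples <- setdiff(names(counts), "gene_id")
    missing <- setdiff(samples, tbl$sample_id)
    if (length(missing)) {
      abort(sprintf("metadata missing sample(s): %s", paste(missing, collapse = ", ")))
    }
  }
  tbl
}

#' Write sample metadata to CSV
#' @param metadata metadata tibble.
#' @param path output path.
#' @export
write_metadata <- function(metadata, path) write_with_schema(metadata, path, ",")

#' Read gene annotation (TSV)
#'
#' Required: gene_id, length_bp. Optional: gc_fraction, cgi_status,
#' transcript_length_median/min/max/canonical.
#'
#' @param path TSV file path.
#' @return validated annotation tibble.
#' @export
read_annotation <- function(path) {
  tbl <- read_table_checked(
    path, "\t", c("gene_id", "length_bp"),
    numeric_cols = c("length_bp", "gc_fraction", "transcript_length_median",
                     "transcript_length_min", "transcript_length_max",
                     "transcript_length_canonical")
  )
  if (anyDuplicated(tbl$gene_id)) {
    abort(sprintf("duplicate gene_id: %s", tbl$gene_id[duplicated(tbl$gene_id)][1L]))
  }
  if (any(is.na(tbl$length_bp) | tbl$length_bp <= 0)) {
    abort(sprintf("non-positive length_bp for gene '%s'",
                  tbl$gene_id[which(is.na(tbl$length_bp) | tbl$length_bp <= 0)[1L]]))
  }
  if (all(c("transcript_length_min", "transcript_length_median",
            "transcript_length_max") %in% names(tbl))) {
    ok <- is.na(tbl$transcript_length_min) | is.na(tbl$transcript_length_median) |
      is.na(tbl$transcript_length_max) |
      (tbl$transcript_length_min <= tbl$transcript_length_median &
         tbl$transcript_length_median <= tbl$transcript_length_max)
    if (!all(ok)) {
      abort(sprintf("transcript length min/median/max out of order for gene '%s'",
                    tbl$gene_id[which(!ok)[1L]]))
    }
  }
  if ("cgi_status" %in% names(tbl)) {
    bad <- setdiff(unique(tbl$cgi_status[!is.na(tbl$cgi_status)]),
                   c("CGI+", "CGI-", "unknown"))
    if (length(bad)) abort(sprintf("unknown cgi_status label(s): %s", paste(bad, collapse = ", ")))
  }
  tbl
}

#' Write gene annotation to TSV
#' @param annotation annotation tibble.
#' @param path output path.
#' @export
write_annotation <- function(annotation, path) write_with_schema(annotation, path, "\t")

#' Read an RT-qPCR Ct table (CSV: sample_id, group, one column per gene)
#'
#' @param path CSV file path.
#' @return validated Ct tibble.
#' @export
read_ct_table <- function(path) {
  tbl <- read_table_checked(path, ",", c("sample_id", "group"))
  gene_cols <- setdiff(names(tbl), c("sample_id", "group"))
  if (length(gene_cols) < 2L) abort("Ct table needs at least 2 gene columns")
  for (g in gene_cols) {
    tbl[[g]] <- as.numeric(tbl[[g]])
    if (any(!is.finite(tbl[[g]]))) {
      abort(sprintf("non-finite Ct for gene '%s', sample '%s'", g,
                    tbl$sample_id[which(!is.finite(tbl[[g]]))[1L]]))
    }
  }
  tbl
}

#' Write a Ct table to CSV
#' @param ct Ct tibble.
#' @param path output path.
#' @export
write_ct_table <- function(ct, path) write_with_schema(ct, path, ",")

#' Write the planted-truth table (TSV, parameters JSON-encoded)
#' @param truth truth tibble from [simulate_cohort()].
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  par_cols <- setdiff(names(truth), c("gene_id", "class_label"))
  out <- tibble(
    gene_id = truth$gene_id,
    class_label = truth$class_label,
    parameters = vapply(seq_len(nrow(truth)), function(i) {
      as.character(jsonlite::toJSON(as.list(truth[i, par_cols]), auto_unbox = TRUE, digits = NA))
    }, character(1))
  )
  write_with_schema(out, path, "\t")
}

#' Write per-tissue filter reports and the survivor-count summary
#'
#' One TSV per tissue holding, per gene and normalization, the summary
#' statistics and the raw per-step pass flags plus the combined final
#' verdict; statistics of zero-containing genes are written as empty
#' fields. A `filter_counts.tsv` summary holds survivors per step per
#' tissue.
#'
#' @param pipeline an `rg_pipeline`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_filter_report <- function(pipeline, dir) {
  stopifnot(inherits(pipeline, "rg_pipeline"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (tis in pipeline$tissues) {
    rep_tbl <- pipeline$stats %>%
      filter(.data$tissue == .env$tis) %>%
      left_join(pipeline$flags, by = c("gene_id", "tissue", "normalization")) %>%
      left_join(pipeline$filters %>% select("gene_id", "tissue", "final"),
                by = c("gene_id", "tissue")) %>%
      arrange(.data$gene_id, .data$normalization)
    p <- file.path(dir, sprintf("%s_filter_report.tsv", tis))
    write_with_schema(rep_tbl, p, "\t")
    paths <- c(paths, p)
  }
  p <- file.path(dir, "filter_counts.tsv")
  write_with_schema(pipeline$survivor_counts, p, "\t")
  invisible(c(paths, p))
}

#' Write cumulative per-step gene lists per tissue
#'
#' One TSV per tissue with columns `step` and `gene_id` listing the genes
#' that survive through each consecutive step (genes sorted
#' lexicographically).
#'
#' @inheritParams write_filter_report
#' @export
write_gene_lists <- function(pipeline, dir) {
  stopifnot(inherits(pipeline, "rg_pipeline"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (tis in pipeline$tissues) {
    sub <- pipeline$filters %>% filter(.data$tissue == .env$tis)
    lists <- lapply(1:6, function(k) {
      g <- sort(sub$gene_id[sub[[paste0("f", k)]]])
      if (length(g)) tibble(step = k, gene_id = g) else NULL
    })
    out <- bind_rows(lists)
    if (is.null(out) || !nrow(out)) out <- tibble(step = integer(), gene_id = character())
    p <- file.path(dir, sprintf("%s_gene_lists.tsv", tis))
    write_with_schema(out, p, "\t")
    paths <- c(paths, p)
  }
  invisible(paths)
}
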