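# Readers and writers for the plain-text interchange formats: wide counts
# TSV, sample metadata TSV, long junction-read TSV and GMT gene sets.

#' Read a wide counts table
#'
#' @param path TSV with header `feature_id` plus one column per sample.
#' @return Wide tibble of integer counts.
#' @export
read_counts_tsv <- function(path) {
  if (!file.exists(path)) abort(sprintf("counts file not found: '%s'", path))
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot_cols(out, "feature_id", path)
  out
}

#' Read a sample metadata table
#'
#' @param path TSV with columns `sample_id`, `chemical`, `dose_uM`,
#'   `replicate`.
#' @return Design tibble (a `dose_label` column is re-derived).
#' @export
read_metadata_tsv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("metadata file not found: '%s'", path))
  }
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot_cols(out, c("sample_id", "chemical", "dose_uM", "replicate"),
                 path)
  out$replicate <- as.integer(out$replicate)
  dplyr::relocate(
    dplyr::mutate(out, dose_label = format_dose(.data$dose_uM)),
    "sample_id", "chemical", "dose_uM", "dose_label", "replicate"
  )
}

#' Read a long splicing event table
#'
#' @param path TSV with columns `event_id`, `gene_id`, `event_type`,
#'   `sample_id`, `inc_reads`, `exc_reads`.
#' @return Long tibble of junction reads.
#' @export
read_events_tsv <- function(path) {
  if (!file.exists(path)) abort(sprintf("events file not found: '%s'", path))
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot_cols(out, c("event_id", "gene_id", "event_type", "sample_id",
                        "inc_reads", "exc_reads"), path)
  out$inc_reads <- as.integer(out$inc_reads)
  out$exc_reads <- as.integer(out$exc_reads)
  out
}

#' Read gene sets in GMT format
#'
#' Standard tab-separated dialect: set name, description (may be empty), then
#' one gene per remaining field. Duplicate genes within a set are dropped.
#'
#' @param path GMT file path.
#' @return Gene-set tibble: `set_name`, `description`, `genes` (list column).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("GMT file not found: '%s'", path))
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 2
  if (any(bad)) {
    abort(sprintf("malformed GMT line(s) in '%s': %s", path,
                  paste(which(bad), collapse = ", ")))
  }
  tibble(
    set_name = vapply(parts, `[`, character(1), 1),
    description = vapply(parts, `[`, character(1), 2),
    genes = lapply(parts, function(p) unique(p[-(1:2)]))
  )
}

#' Write gene sets in GMT format
#'
#' @param gene_sets Gene-set tibble as returned by [read_gmt()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(gene_sets, path) {
  stopifnot_cols(gene_sets, c("set_name", "description", "genes"),
                 "gene_sets")
  lines <- purrr::pmap_chr(gene_sets, function(set_name, description, genes,
                                               ...) {
    paste(c(set_name, description, genes), collapse = "\t")
  })
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a feature truth table written by [write_fixtures()]
#'
#' @param path TSV path; the `curve_params` column holds comma-joined
#'   numeric vectors.
#' @return Feature truth tibble with `curve_params` restored to a list
#'   column.
#' @export
read_feature_truth_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot_cols(out, c("feature_id", "curve_family", "curve_params"), path)
  out$curve_params <- lapply(strsplit(out$curve_params, ",", fixed = TRUE),
                             as.numeric)
  out
}
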