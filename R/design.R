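#' Build a half-log dose design
#'
#' Constructs the standard in vitro dose-response layout: a vehicle control
#' (dose 0) plus `n_positive_doses` concentrations descending from
#' `top_dose_uM` in half-log steps (factor sqrt(10)), each with
#' `n_replicates` biological replicates. Doses are stored unrounded;
#' 3-significant-figure rounding (0.316, 3.16, 31.6, ...) is applied only to
#' the display labels and sample ids.
#'
#' @param top_dose_uM Highest tested concentration in uM (> 0).
#' @param n_positive_doses Number of positive concentrations (>= 2 for a
#'   half-log series; 1 is allowed for degenerate designs).
#' @param n_replicates Biological replicates per dose group (>= 1).
#' @param chemical Chemical label used in sample ids.
#' @return A tibble with one row per sample and columns `sample_id`,
#'   `chemical`, `dose_uM`, `dose_label`, `replicate`. Rows are ordered by
#'   ascending dose, then replicate.
#' @examples
#' design <- build_design(1000, 9, 4, "diazinon")
#' dose_levels(design)  # 0, 0.1, 0.316, ..., 1000 (labels rounded)
#' @export
build_design <- function(top_dose_uM, n_positive_doses, n_replicates,
                         chemical = "chemical") {
  if (!is.numeric(top_dose_uM) || length(top_dose_uM) != 1 ||
      !is.finite(top_dose_uM) || top_dose_uM <= 0) {
    abort("`top_dose_uM` must be a single positive number")
  }
  if (n_positive_doses < 1 || n_positive_doses != round(n_positive_doses)) {
    abort("`n_positive_doses` must be a positive integer")
  }
  if (n_replicates < 1 || n_replicates != round(n_replicates)) {
    abort("`n_replicates` must be a positive integer")
  }
  # descending by sqrt(10) from the top, then re-sorted ascending
  doses <- top_dose_uM / sqrt(10)^(seq_len(n_positive_doses) - 1)
  doses <- c(0, sort(doses))
  grid <- tidyr::expand_grid(dose_uM = doses,
                             replicate = seq_len(n_replicates))
  labels <- format_dose(grid$dose_uM)
  tibble(
    sample_id = sprintf("%s_d%s_r%d", chemical, labels, grid$replicate),
    chemical = chemical,
    dose_uM = grid$dose_uM,
    dose_label = labels,
    replicate = as.integer(grid$replicate)
  )
}

#' Distinct doses of a design, ascending
#'
#' @param design A design tibble from [build_design()] (or any table with a
#'   `dose_uM` column).
#' @return Numeric vector of unique doses, ascending, control (0) first.
#' @export
dose_levels <- function(design) {
  stopifnot_cols(design, "dose_uM", "design")
  sort(unique(design$dose_uM))
}

# samples belonging to one dose group
samples_at_dose <- function(design, dose) {
  design$sample_id[design$dose_uM == dose]
}

validate_design <- function(design) {
  stopifnot_cols(design, c("sample_id", "chemical", "dose_uM", "replicate"),
                 "design")
  if (anyDuplicated(design$sample_id)) {
    abort("design has duplicated sample ids")
  }
  doses <- dose_levels(design)
  if (doses[1] != 0) abort("design must include a vehicle control (dose 0)")
  invisible(design)
}
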