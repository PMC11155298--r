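# ggplot2 displays for the standard result types. These are conveniences;
# all underlying tables are returned by the analysis functions themselves.

#' Plot a fitted dose-response curve over the group means
#'
#' @param object A `dr_fit` object.
#' @param ... Unused.
#' @return A ggplot: observed dose-group means and the fitted curve on a
#'   log10 dose axis (control plotted at a pseudo-dose below the lowest
#'   positive dose).
#' @export
autoplot.dr_fit <- function(object, ...) {
  gs <- object$stats
  curve <- augment.dr_fit(object)
  dmin <- min(gs$dose[gs$dose > 0])
  shift <- function(d) ifelse(d == 0, dmin / 3, d)
  ggplot2::ggplot(curve, ggplot2::aes(x = shift(.data$dose_uM),
                                      y = .data$fitted)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(
      data = tibble(dose_uM = gs$dose, ybar = gs$ybar),
      ggplot2::aes(x = shift(.data$dose_uM), y = .data$ybar)
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose (uM, control at left edge)",
                  y = "log2 response",
                  title = sprintf("%s fit", object$family))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' BMD accumulation plot
#'
#' @param curves Named list of BMD value vectors (one per condition), or a
#'   single numeric vector.
#' @return A ggplot step curve of the number of features/pathways with BMD
#'   at or below each dose.
#' @export
plot_accumulation <- function(curves) {
  if (is.numeric(curves)) curves <- list(values = curves)
  df <- purrr::imap_dfr(curves, function(v, nm) {
    dplyr::mutate(accumulation_curve(v), condition = nm)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dose_uM,
                                   y = .data$n_accumulated,
                                   color = .data$condition)) +
    ggplot2::geom_step() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose (uM)", y = "features with BMD <= dose",
                  title = "BMD accumulation")
}

#' Expression-versus-splicing pathway BMD scatter
#'
#' @param modality_pairs Paired table from
#'   [compare_modalities_and_overlaps()].
#' @return A ggplot scatter of pathway mean BMDs, intron-derived on x,
#'   expression-derived on y, with the identity line.
#' @export
plot_modality_scatter <- function(modality_pairs) {
  stopifnot_cols(modality_pairs,
                 c("set_name", "expression_mean_bmd", "intron_mean_bmd"),
                 "modality_pairs")
  ggplot2::ggplot(modality_pairs,
                  ggplot2::aes(x = .data$intron_mean_bmd,
                               y = .data$expression_mean_bmd)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey50") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "intron-derived pathway mean BMD (uM)",
                  y = "expression-derived pathway mean BMD (uM)")
}
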