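# broom-style accessors for fitted dose-response models

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the parameters of a fitted dose-response model
#'
#' @param x A `dr_fit` object.
#' @param ... Unused.
#' @return Tibble with one row per mean parameter (`term`, `estimate`) plus
#'   the residual SD as term `sigma`.
#' @export
tidy.dr_fit <- function(x, ...) {
  tibble(
    term = c(names(x$theta), "sigma"),
    estimate = c(unname(x$theta), x$sigma_hat)
  )
}

#' One-row fit summary of a dose-response model
#'
#' @param x A `dr_fit` object.
#' @param ... Unused.
#' @return One-row tibble: `family`, `n_obs`, `n_params`, `sigma_hat`,
#'   `loglik`, `aic`, `converged`.
#' @export
glance.dr_fit <- function(x, ...) {
  tibble(family = x$family, n_obs = x$n_obs, n_params = x$n_params,
         sigma_hat = x$sigma_hat, loglik = x$loglik, aic = x$aic,
         converged = x$converged)
}

#' Fitted curve with observed group means, for plotting or inspection
#'
#' @param x A `dr_fit` object.
#' @param n_grid Points on the dose grid (default 100, log-spaced over the
#'   positive range plus control).
#' @param ... Unused.
#' @return Tibble: `dose_uM`, `fitted`.
#' @export
augment.dr_fit <- function(x, n_grid = 100, ...) {
  dmax <- max(x$stats$dose)
  dmin <- min(x$stats$dose[x$stats$dose > 0])
  grid <- c(0, exp(seq(log(dmin / 3), log(dmax), length.out = n_grid - 1)))
  tibble(dose_uM = grid, fitted = predict_fit(x, grid))
}

#' @importFrom generics augment
#' @export
generics::augment
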