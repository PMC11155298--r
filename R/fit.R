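# Constant-variance maximum-likelihood fitting of continuous dose-response
# models.
#
# All models share a single residual SD across dose groups (the data are on
# the log2 scale). The normal likelihood is profiled over sigma
# (sigma^2 = RSS / n), so fitting reduces to residual-sum-of-squares
# minimization: exact weighted least squares on dose-group means for the
# polynomial families, seeded multi-start bounded optimization for the
# nonlinear ones. Group-level sufficient statistics (group sizes, means and
# the pooled within-group SS) make every RSS evaluation O(#dose groups).

MODEL_FAMILIES <- c("linear", "poly2", "poly3", "power", "hill", "exp3")
POLY_FAMILIES <- c("linear", "poly2", "poly3")

# sufficient statistics of (dose, response) data under constant variance
group_stats <- function(data) {
  stopifnot_cols(data, c("dose", "response"), "data")
  if (any(!is.finite(data$response)) || any(!is.finite(data$dose))) {
    abort("doses and responses must be finite")
  }
  agg <- dplyr::summarise(
    dplyr::group_by(data, dose = .data$dose),
    n = dplyr::n(), ybar = mean(.data$response),
    ss = sum((.data$response - mean(.data$response))^2), .groups = "drop"
  )
  agg <- dplyr::arrange(agg, .data$dose)
  list(dose = agg$dose, n_g = agg$n, ybar = agg$ybar,
       ss_within = sum(agg$ss), n = sum(agg$n),
       y_scale = max(abs(agg$ybar), 1))
}

rss_from_mu <- function(gs, mu) {
  gs$ss_within + sum(gs$n_g * (mu - gs$ybar)^2)
}

# exact log-likelihood at the profiled sigma^2 = RSS/n
loglik_from_rss <- function(rss, n) {
  # RSS floored at n * 1e-24 (sigma floor 1e-12) so exact and
  # numerically-zero interpolations share one degenerate likelihood
  -n / 2 * (log(2 * pi * max(rss, n * 1e-24) / n) + 1)
}

# optimizer-internal parameterizations: hill and exp3 carry their dose-scale
# parameter on the log scale for conditioning; natural parameters are stored
# on the fit object.
opt_to_natural <- function(family, theta) {
  switch(family,
    hill = c(v0 = theta[[1]], v = theta[[2]], k = exp(theta[[3]]),
             n = theta[[4]]),
    exp3 = c(a = theta[[1]], b = theta[[2]], c = exp(theta[[3]])),
    power = c(a = theta[[1]], b = theta[[2]], p = theta[[3]]),
    setNames(theta, paste0("b", seq_along(theta) - 1))
  )
}

natural_to_opt <- function(family, theta) {
  theta <- unname(theta)
  switch(family,
    hill = c(theta[1], theta[2], log(theta[3]), theta[4]),
    exp3 = c(theta[1], theta[2], log(theta[3])),
    theta
  )
}

eval_opt_curve <- function(family, theta, dose, dose_scale) {
  eval_curve(family, opt_to_natural(family, theta), dose, dose_scale)
}

# parameter boxes and heuristic starts for the nonlinear families
nl_setup <- function(family, gs, dose_scale, power_lower = 1,
                     hill_n_lower = 1) {
  ymin <- min(gs$ybar); ymax <- max(gs$ybar)
  s <- ymax - ymin + 1e-6
  delta <- gs$ybar[length(gs$ybar)] - gs$ybar[1]
  d_pos <- gs$dose[gs$dose > 0]
  # k may fall well below the lowest tested dose (that regime is what the
  # Hill-k flag screens for), so the box reaches far under the dose range
  lk <- log(c(dose_scale * 1e-6, dose_scale * 100))
  switch(family,
    hill = list(
      lower = c(ymin - s, -2 * s, lk[1], hill_n_lower),
      upper = c(ymax + s, 2 * s, lk[2], 18),
      start = c(gs$ybar[1], delta, log(median(d_pos)), 1.5)
    ),
    power = list(
      lower = c(ymin - s, -2 * s, power_lower),
      upper = c(ymax + s, 2 * s, 18),
      start = c(gs$ybar[1], delta, max(1, power_lower))
    ),
    exp3 = list(
      lower = c(ymin - s, -4 * s, log(dose_scale * 1e-3)),
      upper = c(ymax + s, 4 * s, log(dose_scale * 100)),
      start = c(gs$ybar[1], delta, log(dose_scale / 3))
    ),
    abort(sprintf("no nonlinear setup for family '%s'", family))
  )
}

fit_poly <- function(gs, degree) {
  X <- outer(gs$dose, 0:degree, `^`)
  w <- gs$n_g
  fit <- stats::lm.wfit(X, gs$ybar, w)
  theta <- unname(fit$coefficients)
  theta[is.na(theta)] <- 0
  theta
}

#' Fit one dose-response model by constant-variance maximum likelihood
#'
#' Polynomial families are solved exactly by weighted least squares on the
#' dose-group means; `power`, `hill` and `exp3` use seeded multi-start
#' bounded optimization (`nlminb`) of the residual sum of squares, with the
#' first start at a heuristic and the rest drawn uniformly inside the
#' parameter box. The likelihood is profiled over sigma, so
#' `sigma_hat^2 = RSS / n` exactly.
#'
#' @param data Tibble with columns `dose` and `response` (log2 scale), one
#'   row per sample.
#' @param family One of `"linear"`, `"poly2"`, `"poly3"`, `"power"`,
#'   `"hill"`, `"exp3"`.
#' @param n_starts Number of optimizer starts for nonlinear families
#'   (default 10).
#' @param seed RNG seed for the random starts (default 1).
#' @param power_lower Lower bound of the power exponent (default 1; set 0 to
#'   allow sublinear onset).
#' @param hill_n_lower Lower bound of the Hill coefficient (default 1).
#' @return A `dr_fit` object: family, natural parameters, `sigma_hat`,
#'   `loglik`, `aic` (`2 * n_params - 2 * loglik`, with `n_params` counting
#'   the mean parameters plus one variance parameter), convergence flag and
#'   the group sufficient statistics.
#' @export
fit_model <- function(data, family, n_starts = 10, seed = 1,
                      power_lower = 1, hill_n_lower = 1) {
  family <- match.arg(family, MODEL_FAMILIES)
  gs <- group_stats(data)
  n_mean <- n_mean_params(family)
  if (gs$n < n_mean + 1) {
    abort(sprintf("family '%s' needs at least %d observations",
                  family, n_mean + 1))
  }
  dose_scale <- max(gs$dose)
  if (dose_scale <= 0) abort("at least one positive dose required")
  if (family %in% POLY_FAMILIES) {
    theta_opt <- fit_poly(gs, n_mean - 1)
    rss <- rss_from_mu(gs, eval_opt_curve(family, theta_opt, gs$dose,
                                          dose_scale))
    converged <- TRUE
  } else {
    su <- nl_setup(family, gs, dose_scale, power_lower, hill_n_lower)
    start0 <- pmin(pmax(su$start, su$lower), su$upper)
    starts <- list(start0)
    if (n_starts > 1) {
      rand <- with_seed(seed, {
        matrix(runif((n_starts - 1) * length(su$lower)), n_starts - 1)
      })
      for (i in seq_len(n_starts - 1)) {
        starts[[i + 1]] <- su$lower + rand[i, ] * (su$upper - su$lower)
      }
    }
    obj <- function(th) {
      rss_from_mu(gs, eval_opt_curve(family, th, gs$dose, dose_scale))
    }
    best <- NULL
    for (st in starts) {
      res <- tryCatch(
        nlminb(st, obj, lower = su$lower, upper = su$upper,
               control = list(iter.max = 500, eval.max = 1000,
                              rel.tol = 1e-12)),
        error = function(e) NULL
      )
      if (!is.null(res) &&
          (is.null(best) || res$objective < best$objective)) {
        best <- res
      }
    }
    converged <- !is.null(best) && is.finite(best$objective)
    if (!converged) {
      theta_opt <- start0
      rss <- obj(start0)
    } else {
      theta_opt <- best$par
      rss <- best$objective
    }
  }
  n_params <- n_mean + 1L  # + the variance parameter
  ll <- loglik_from_rss(rss, gs$n)
  structure(list(
    family = family,
    theta = opt_to_natural(family, theta_opt),
    theta_opt = theta_opt,
    dose_scale = dose_scale,
    sigma_hat = sqrt(rss / gs$n),
    rss = rss,
    loglik = ll,
    aic = 2 * n_params - 2 * ll,
    n_params = n_params,
    n_mean_params = n_mean,
    n_obs = gs$n,
    converged = converged,
    stats = gs,
    bounds = if (family %in% POLY_FAMILIES) NULL else
      nl_setup(family, gs, dose_scale, power_lower, hill_n_lower)
  ), class = "dr_fit")
}

#' Predicted response of a fitted dose-response model
#'
#' @param fit A `dr_fit` object.
#' @param dose Numeric dose vector.
#' @return Predicted log2 responses.
#' @export
predict_fit <- function(fit, dose) {
  eval_curve(fit$family, fit$theta, dose, fit$dose_scale)
}

#' Fit the full model suite to one feature
#'
#' @inheritParams fit_model
#' @param families Model families to fit (default all six).
#' @return Named list of `dr_fit` objects (non-fitting families dropped with
#'   a message).
#' @export
fit_all_models <- function(data, families = MODEL_FAMILIES, n_starts = 10,
                           seed = 1, power_lower = 1, hill_n_lower = 1) {
  fits <- list()
  for (fam in families) {
    f <- tryCatch(
      fit_model(data, fam, n_starts = n_starts, seed = seed,
                power_lower = power_lower, hill_n_lower = hill_n_lower),
      error = function(e) NULL
    )
    if (!is.null(f)) fits[[fam]] <- f
  }
  fits
}

#' @export
print.dr_fit <- function(x, ...) {
  cat(sprintf("<dr_fit> %s model, %d obs\n", x$family, x$n_obs))
  cat("  theta:", paste(sprintf("%s=%.4g", names(x$theta), x$theta),
                        collapse = ", "), "\n")
  cat(sprintf("  sigma_hat=%.4g  loglik=%.4f  AIC=%.4f  converged=%s\n",
              x$sigma_hat, x$loglik, x$aic, x$converged))
  invisible(x)
}
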