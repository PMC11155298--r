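# Benchmark-dose derivation: model selection (nested chi-square across the
# polynomial ladder, then AIC against the nonlinear families, with the
# Hill-k flag), goodness of fit against the saturated group-means model,
# the 1-SD benchmark response root, profile-likelihood BMDL/BMDU, and the
# three rejection filters.

# likelihood-ratio statistic between two nested constant-variance fits with
# sigma profiled out: n * log(RSS0 / RSS1)
lr_stat <- function(rss0, rss1, n, scale = 1) {
  eps <- n * 1e-14 * scale^2
  if (rss1 <= eps) {
    if (rss0 <= rss1 + eps) return(0)
    return(Inf)
  }
  max(0, n * log(rss0 / rss1))
}

#' Goodness of fit against the saturated group-means model
#'
#' Likelihood-ratio test of the fitted model against the "full" model with a
#' separate mean per dose group and a common sigma. The statistic
#' `2 * (ll_full - ll_model)` is referred to a chi-square with
#' `#dose groups - #mean parameters` degrees of freedom; a non-positive df
#' gives p = 1 by convention.
#'
#' @param fit A `dr_fit` object.
#' @return Goodness-of-fit p-value.
#' @export
goodness_of_fit <- function(fit) {
  if (!fit$converged) abort("goodness of fit requires a converged fit")
  gs <- fit$stats
  df <- length(gs$dose) - fit$n_mean_params
  if (df <= 0) return(1)
  stat <- lr_stat(fit$rss, gs$ss_within, gs$n, gs$y_scale)
  pchisq(stat, df, lower.tail = FALSE)
}

#' Select the best dose-response model
#'
#' Follows the standard continuous-modeling recipe: (1) climb the polynomial
#' ladder (linear, quadratic, cubic), preferring the higher adjacent degree
#' only when the nested likelihood-ratio chi-square (df = 1) has
#' `p < nested_alpha`; (2) compare the winning polynomial with the converged
#' nonlinear fits by lowest AIC; (3) if the winner is a Hill model whose
#' half-max dose `k` is below one third of the lowest positive dose, flag it
#' and fall back to the lowest-AIC unflagged model whose goodness-of-fit p
#' exceeds `gof_alpha`; when none qualifies the flagged Hill is returned.
#'
#' @param fits Named list of `dr_fit` objects from [fit_all_models()].
#' @param lowest_positive_dose Lowest positive tested dose (uM).
#' @param nested_alpha Significance level of the nested polynomial test
#'   (default 0.05).
#' @param gof_alpha Goodness-of-fit level used by the Hill-flag fallback
#'   (default 0.05).
#' @return List with elements `fit` (the selected `dr_fit`, or `NULL` when
#'   nothing converged), `hill_flagged` (was the Hill winner flagged) and
#'   `fallback_used`.
#' @export
select_best_model <- function(fits, lowest_positive_dose,
                              nested_alpha = 0.05, gof_alpha = 0.05) {
  fits <- fits[vapply(fits, function(f) isTRUE(f$converged), logical(1))]
  if (!length(fits)) {
    return(list(fit = NULL, hill_flagged = FALSE, fallback_used = FALSE))
  }
  polys <- intersect(POLY_FAMILIES, names(fits))
  winner <- NULL
  if (length(polys)) {
    winner <- fits[[polys[1]]]
    for (fam in polys[-1]) {
      cand <- fits[[fam]]
      if (cand$n_mean_params != winner$n_mean_params + 1) break
      stat <- lr_stat(winner$rss, cand$rss, winner$n_obs,
                      winner$stats$y_scale)
      if (pchisq(stat, 1, lower.tail = FALSE) < nested_alpha) {
        winner <- cand
      } else {
        break  # stop at the first non-significant adjacent step
      }
    }
  }
  candidates <- c(if (!is.null(winner)) list(winner),
                  unname(fits[setdiff(names(fits), POLY_FAMILIES)]))
  aics <- vapply(candidates, `[[`, numeric(1), "aic")
  nps <- vapply(candidates, `[[`, numeric(1), "n_params")
  best <- candidates[[order(aics, nps)[1]]]
  hill_flagged <- FALSE
  fallback_used <- FALSE
  if (best$family == "hill" &&
      best$theta[["k"]] < lowest_positive_dose / 3) {
    hill_flagged <- TRUE
    alts <- candidates[vapply(candidates, function(f) f$family != "hill",
                              logical(1))]
    alts <- alts[vapply(alts, function(f) goodness_of_fit(f) > gof_alpha,
                        logical(1))]
    if (length(alts)) {
      aics <- vapply(alts, `[[`, numeric(1), "aic")
      best <- alts[[which.min(aics)]]
      fallback_used <- TRUE
    }
  }
  list(fit = best, hill_flagged = hill_flagged,
       fallback_used = fallback_used)
}

#' Benchmark dose at a 1-SD benchmark response
#'
#' The adverse direction is the sign of `f(max dose) - f(0)`; the BMD is the
#' smallest positive dose at which the fitted curve departs from its control
#' value by `bmr` (default: the fitted residual SD, the 1-SD benchmark
#' response), located by bracketing on a log grid and refined by root
#' finding to ~1e-8 relative. Returns `NA` when the curve never moves one
#' SD inside `(0, max dose]`.
#'
#' @param fit A `dr_fit` object.
#' @param bmr Benchmark response in log2 units (default `fit$sigma_hat`).
#' @param max_dose Upper end of the search range (default: top fitted dose).
#' @return Named list: `bmd` (uM or `NA`) and `adverse_direction`
#'   (`"up"`/`"down"`).
#' @export
compute_bmd <- function(fit, bmr = NULL, max_dose = NULL) {
  max_dose <- max_dose %||% max(fit$stats$dose)
  bmr <- bmr %||% fit$sigma_hat
  f0 <- predict_fit(fit, 0)
  delta_top <- predict_fit(fit, max_dose) - f0
  direction <- if (delta_top < 0) "down" else "up"
  if (!is.finite(bmr) || bmr <= 0) {
    return(list(bmd = NA_real_, adverse_direction = direction))
  }
  g <- function(d) abs(predict_fit(fit, d) - f0) - bmr
  grid <- c(0, exp(seq(log(max_dose * 1e-9), log(max_dose),
                       length.out = 500)))
  vals <- g(grid)
  idx <- which(vals[-1] >= 0 & vals[-length(vals)] < 0)
  if (!length(idx)) {
    return(list(bmd = NA_real_, adverse_direction = direction))
  }
  i <- idx[1]
  lo <- max(grid[i], max_dose * 1e-12)
  root <- uniroot(g, lower = lo, upper = grid[i + 1],
                  tol = max_dose * 1e-12)$root
  list(bmd = root, adverse_direction = direction)
}

# profile log-likelihood at a candidate BMD b: maximize over the mean
# parameters with sigma tied to the benchmark-response constraint
# sigma = |f(b) - f(0)| (the 1-SD BMR definition makes sigma an explicit
# function of the curve at b, so the BMD becomes the profiled parameter).
profile_ll_at <- function(fit, b, start) {
  gs <- fit$stats
  n <- gs$n
  fam <- fit$family
  ds <- fit$dose_scale
  obj <- function(th) {
    mu <- eval_opt_curve(fam, th, gs$dose, ds)
    sig <- abs(eval_opt_curve(fam, th, b, ds) -
                 eval_opt_curve(fam, th, 0, ds))
    if (!is.finite(sig) || sig < 1e-12) return(1e10)
    rss <- rss_from_mu(gs, mu)
    n / 2 * log(2 * pi * sig^2) + rss / (2 * sig^2)
  }
  lower <- if (is.null(fit$bounds)) rep(-Inf, length(start)) else
    fit$bounds$lower
  upper <- if (is.null(fit$bounds)) rep(Inf, length(start)) else
    fit$bounds$upper
  res <- tryCatch(
    nlminb(start, obj, lower = lower, upper = upper,
           control = list(iter.max = 300, eval.max = 600, rel.tol = 1e-12)),
    error = function(e) NULL
  )
  if (is.null(res)) return(list(ll = -Inf, par = start))
  list(ll = -res$objective, par = res$par)
}

#' Profile-likelihood confidence bounds on the benchmark dose
#'
#' Treats the BMD as the profiled parameter (sigma is tied to the 1-SD
#' benchmark-response constraint) and finds the candidate doses at which
#' twice the profile log-likelihood drop reaches the chi-square(1) quantile
#' at `2 * confidence - 1` — one-sided `confidence` per bound, the
#' conventional continuous-BMD procedure. The search expands geometrically
#' from the BMD and closes each bound by bisection; a side that fails to
#' close inside `(0, 10 * max dose]` is returned as `NA` (and downstream
#' treated as an infinite BMDU/BMDL ratio).
#'
#' @param fit A `dr_fit` object (converged, with a defined BMD).
#' @param bmd The benchmark dose from [compute_bmd()].
#' @param confidence One-sided confidence per bound (default 0.95).
#' @return Named list `bmdl`, `bmdu` (uM, possibly `NA`).
#' @export
profile_interval <- function(fit, bmd, confidence = 0.95) {
  if (!is.finite(bmd) || bmd <= 0) {
    return(list(bmdl = NA_real_, bmdu = NA_real_))
  }
  cutoff <- qchisq(2 * confidence - 1, 1)
  max_dose <- max(fit$stats$dose)
  # the unconstrained maximum: at b = bmd the constraint sigma = |df(bmd)|
  # holds at the MLE itself, so the profile peaks at the fitted loglik
  ll_hat <- fit$loglik
  warm <- fit$theta_opt
  stat_at <- function(b) {
    res <- profile_ll_at(fit, b, warm)
    warm <<- res$par
    max(0, 2 * (ll_hat - res$ll))
  }
  search_bound <- function(side) {
    warm <<- fit$theta_opt
    limit_hit <- function(b) {
      if (side == "lower") b < bmd * 1e-6 else b > 10 * max_dose
    }
    b_in <- bmd
    s_in <- 0
    b_out <- bmd
    repeat {
      b_out <- if (side == "lower") b_out / 2 else b_out * 2
      if (limit_hit(b_out)) return(NA_real_)
      s_out <- stat_at(b_out)
      if (s_out >= cutoff) break
      b_in <- b_out
      s_in <- s_out
    }
    # bisection on the log scale between the inner and outer bracket
    for (it in 1:40) {
      b_mid <- sqrt(b_in * b_out)
      s_mid <- stat_at(b_mid)
      if (s_mid >= cutoff) b_out <- b_mid else b_in <- b_mid
      if (abs(log(b_out / b_in)) < 1e-5) break
    }
    sqrt(b_in * b_out)
  }
  list(bmdl = search_bound("lower"), bmdu = search_bound("upper"))
}

#' Apply the three BMD rejection filters
#'
#' A result passes when its BMD lies within the tested positive dose range,
#' its goodness-of-fit p-value is at least `fit_p_min`, and its BMDU/BMDL
#' ratio is at most `ratio_max`. Failures are labeled with the first failing
#' rule in that order; results without a BMD are `fail_no_bmd`, and an
#' undefined profile bound counts as an infinite ratio.
#'
#' @param results BMD results tibble carrying `bmd`, `bmdl`, `bmdu`,
#'   `fit_p`.
#' @param design Design tibble (defines the tested dose range).
#' @param fit_p_min Minimal goodness-of-fit p (default 0.1).
#' @param ratio_max Maximal BMDU/BMDL ratio (default 40).
#' @return `results` with a `filter_status` column (`pass`, `fail_range`,
#'   `fail_fit_p`, `fail_ratio`, `fail_no_bmd`).
#' @export
apply_result_filters <- function(results, design, fit_p_min = 0.1,
                                 ratio_max = 40) {
  stopifnot_cols(results, c("bmd", "bmdl", "bmdu", "fit_p"), "results")
  doses <- dose_levels(design)
  lo <- min(doses[doses > 0])
  hi <- max(doses)
  ratio <- ifelse(is.finite(results$bmdl) & is.finite(results$bmdu) &
                    results$bmdl > 0, results$bmdu / results$bmdl, Inf)
  status <- dplyr::case_when(
    !is.finite(results$bmd) ~ "fail_no_bmd",
    results$bmd < lo | results$bmd > hi ~ "fail_range",
    results$fit_p < fit_p_min ~ "fail_fit_p",
    ratio > ratio_max ~ "fail_ratio",
    TRUE ~ "pass"
  )
  dplyr::mutate(results, filter_status = status)
}

#' Configuration for BMD batch runs
#'
#' @param families Model families to fit.
#' @param n_starts Optimizer starts per nonlinear family.
#' @param seed Base RNG seed for the optimizer starts.
#' @param confidence One-sided confidence per profile bound.
#' @param fit_p_min,ratio_max Rejection-filter settings.
#' @param nested_alpha,gof_alpha Model-selection settings.
#' @param power_lower,hill_n_lower Parameter bounds (see [fit_model()]).
#' @return A named list of settings for [run_bmd()].
#' @export
bmd_config <- function(families = MODEL_FAMILIES, n_starts = 10, seed = 1,
                       confidence = 0.95, fit_p_min = 0.1, ratio_max = 40,
                       nested_alpha = 0.05, gof_alpha = 0.05,
                       power_lower = 1, hill_n_lower = 1) {
  list(families = families, n_starts = n_starts, seed = seed,
       confidence = confidence, fit_p_min = fit_p_min,
       ratio_max = ratio_max, nested_alpha = nested_alpha,
       gof_alpha = gof_alpha, power_lower = power_lower,
       hill_n_lower = hill_n_lower)
}

#' Batch benchmark-dose analysis of a normalized matrix
#'
#' Runs the full per-feature chain — fit all families, select the best
#' model, goodness of fit, 1-SD BMD, profile interval, rejection filters —
#' over every feature of a normalized log2 matrix (typically the
#' prefilter-passing subset). Per-feature failures are caught and reported
#' as `fail_no_bmd` rows; the batch never aborts.
#'
#' @param mat Normalized wide tibble from [normalize_matrix()].
#' @param design Design tibble.
#' @param config Settings list from [bmd_config()].
#' @param modality Label attached to every row (e.g. `"expression"` or
#'   `"intron"`).
#' @return Tibble: `feature_id`, `modality`, `best_model`, `bmd`, `bmdl`,
#'   `bmdu`, `fit_p`, `aic`, `sigma_hat`, `hill_flagged`,
#'   `adverse_direction`, `filter_status`.
#' @export
run_bmd <- function(mat, design, config = bmd_config(),
                    modality = "expression") {
  validate_design(design)
  m <- as_feature_matrix(mat)
  if (nrow(m) == 0) {
    return(tibble(feature_id = character(), modality = character(),
                  best_model = character(), bmd = numeric(),
                  bmdl = numeric(), bmdu = numeric(), fit_p = numeric(),
                  aic = numeric(), sigma_hat = numeric(),
                  hill_flagged = logical(), adverse_direction = character(),
                  filter_status = character()))
  }
  m <- m[, design$sample_id, drop = FALSE]
  rows <- purrr::map_dfr(seq_len(nrow(m)), function(i) {
    fid <- rownames(m)[i]
    res <- tryCatch({
      data <- tibble(dose = design$dose_uM, response = m[i, ])
      fits <- fit_all_models(data, families = config$families,
                             n_starts = config$n_starts,
                             seed = config$seed + i,
                             power_lower = config$power_lower,
                             hill_n_lower = config$hill_n_lower)
      sel <- select_best_model(fits, min(design$dose_uM[design$dose_uM > 0]),
                               nested_alpha = config$nested_alpha,
                               gof_alpha = config$gof_alpha)
      if (is.null(sel$fit)) abort("no converged fit")
      fit <- sel$fit
      gof <- goodness_of_fit(fit)
      bres <- compute_bmd(fit)
      ci <- if (is.finite(bres$bmd)) {
        profile_interval(fit, bres$bmd, confidence = config$confidence)
      } else {
        list(bmdl = NA_real_, bmdu = NA_real_)
      }
      tibble(feature_id = fid, modality = modality,
             best_model = fit$family, bmd = bres$bmd, bmdl = ci$bmdl,
             bmdu = ci$bmdu, fit_p = gof, aic = fit$aic,
             sigma_hat = fit$sigma_hat, hill_flagged = sel$hill_flagged,
             adverse_direction = bres$adverse_direction)
    }, error = function(e) {
      inform(sprintf("feature %s: %s", fid, conditionMessage(e)))
      tibble(feature_id = fid, modality = modality,
             best_model = NA_character_, bmd = NA_real_, bmdl = NA_real_,
             bmdu = NA_real_, fit_p = NA_real_, aic = NA_real_,
             sigma_hat = NA_real_, hill_flagged = FALSE,
             adverse_direction = NA_character_)
    })
    res
  })
  apply_result_filters(rows, design, fit_p_min = config$fit_p_min,
                       ratio_max = config$ratio_max)
}
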