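# Ground-truth tables for the synthetic-data generator.
#
# Every simulated feature carries its generating curve, residual SD and the
# implied true benchmark dose, so parameter-recovery tests can compare the
# fitted BMD against a value that exists independently of the fitting engine.
# The true BMD is defined from the *noiseless* mean curve and the generating
# residual SD: the smallest positive dose at which the mean response departs
# from its control value by one residual SD (the 1-SD benchmark response).

# smallest d in (0, max_dose] with |mu(d) - mu(0)| = sd, or NA if no crossing;
# bracketed on a fine log grid then refined by uniroot to 1e-12 relative.
solve_true_bmd <- function(family, params, residual_sd, max_dose) {
  if (family == "null") return(NA_real_)
  g <- function(d) curve_abs_change(family, params, d) - residual_sd
  lo <- max_dose * 1e-9
  grid <- exp(seq(log(lo), log(max_dose), length.out = 600))
  vals <- g(grid)
  if (vals[1] >= 0) return(grid[1])
  idx <- which(vals[-1] >= 0 & vals[-length(vals)] < 0)
  if (!length(idx)) return(NA_real_)
  i <- idx[1]
  uniroot(g, lower = grid[i], upper = grid[i + 1], tol = max_dose * 1e-13)$root
}

#' Build a feature truth table
#'
#' @param feature_id Character vector of feature ids.
#' @param family Curve family per feature (recycled); see [eval_curve()].
#'   `"null"` features are flat and carry no true BMD.
#' @param params List of numeric parameter vectors, one per feature.
#' @param residual_sd Residual SD in log2 units (> 0, recycled).
#' @param max_dose Top tested dose, bounding the true-BMD search.
#' @return A tibble with columns `feature_id`, `curve_family`, `curve_params`
#'   (list column), `residual_sd`, `direction` (`"up"`/`"down"`, sign of the
#'   response at the top dose relative to control) and `true_bmd` (uM, `NA`
#'   for null features or curves that never move one SD within range).
#' @export
feature_truth <- function(feature_id, family, params, residual_sd, max_dose) {
  n <- length(feature_id)
  family <- rep_len(family, n)
  residual_sd <- rep_len(residual_sd, n)
  if (any(residual_sd <= 0)) abort("`residual_sd` must be positive")
  bad <- setdiff(unique(family), CURVE_FAMILIES)
  if (length(bad)) {
    abort(sprintf("unknown curve family: %s", paste(bad, collapse = ", ")))
  }
  dirs <- character(n)
  bmds <- numeric(n)
  for (i in seq_len(n)) {
    delta <- eval_curve(family[i], params[[i]], max_dose) -
      eval_curve(family[i], params[[i]], 0)
    dirs[i] <- if (delta < 0) "down" else "up"
    bmds[i] <- if (family[i] == "null") NA_real_ else
      solve_true_bmd(family[i], params[[i]], residual_sd[i], max_dose)
  }
  tibble(
    feature_id = feature_id,
    curve_family = family,
    curve_params = params,
    residual_sd = residual_sd,
    direction = dirs,
    true_bmd = bmds
  )
}

#' Random Hill-response feature truths
#'
#' Draws Hill curves `v0 + v * d^n / (k^n + d^n)` with half-max doses spread
#' log-uniformly across the tested range, giving features whose true BMDs
#' fall inside the positive dose range (the recoverable regime).
#'
#' @param n Number of features.
#' @param max_dose Top tested dose (uM).
#' @param k_range Half-max dose range (uM), sampled log-uniformly.
#' @param v0_range Control-level (intercept) range, log2 units.
#' @param v_range Range of the absolute maximal effect, log2 units.
#' @param n_range Hill coefficient range.
#' @param residual_sd Residual SD, log2 units.
#' @param direction `"random"`, `"up"` or `"down"`.
#' @param seed RNG seed (required).
#' @param prefix Feature id prefix.
#' @return A feature truth tibble (see [feature_truth()]).
#' @export
random_hill_truths <- function(n, max_dose, k_range = c(max_dose / 300,
                                                        max_dose / 3),
                               v0_range = c(4, 10), v_range = c(1.5, 3),
                               n_range = c(1, 3), residual_sd = 0.25,
                               direction = "random", seed, prefix = "hill") {
  with_seed(seed, {
    k <- exp(runif(n, log(k_range[1]), log(k_range[2])))
    v0 <- runif(n, v0_range[1], v0_range[2])
    v <- runif(n, v_range[1], v_range[2])
    hn <- runif(n, n_range[1], n_range[2])
    sgn <- switch(direction,
      random = sample(c(-1, 1), n, replace = TRUE),
      up = rep(1, n),
      down = rep(-1, n),
      abort("`direction` must be 'random', 'up' or 'down'")
    )
    params <- purrr::pmap(list(v0, sgn * v, k, hn), function(a, b, c, d) {
      c(a, b, c, d)
    })
    feature_truth(sprintf("%s_%04d", prefix, seq_len(n)), "hill", params,
                  residual_sd, max_dose)
  })
}

#' Flat (null) feature truths
#'
#' @param n Number of features.
#' @param max_dose Top tested dose (uM).
#' @param mean_range Range of flat log2 means.
#' @param residual_sd Residual SD, log2 units.
#' @param seed RNG seed (required).
#' @param prefix Feature id prefix.
#' @return A feature truth tibble with `true_bmd = NA` throughout.
#' @export
null_feature_truths <- function(n, max_dose, mean_range = c(5, 9),
                                residual_sd = 0.25, seed, prefix = "null") {
  with_seed(seed, {
    mu <- runif(n, mean_range[1], mean_range[2])
    feature_truth(sprintf("%s_%04d", prefix, seq_len(n)), "null",
                  as.list(mu), residual_sd, max_dose)
  })
}

# PSI trajectory of one event truth row at the given doses: baseline plus an
# Emax-shaped dose shift, clipped to [0, 100] (clipping warns upstream).
event_psi <- function(baseline_psi, dpsi_max, ed50, hill_n, dose) {
  shift <- dpsi_max * ifelse(dose == 0, 0,
                             dose^hill_n / (ed50^hill_n + dose^hill_n))
  baseline_psi + shift
}

#' Build an event truth table for splicing simulation
#'
#' Each event has a baseline percent-spliced-in and an Emax-shaped dose shift
#' `dpsi_max * d^h / (ed50^h + d^h)`; junction reads are later simulated as
#' binomial draws at the trajectory PSI.
#'
#' @param event_id,gene_id Character vectors (same length).
#' @param event_type One of `"EX"`, `"IR"`, `"ALT3"`, `"ALT5"` (recycled).
#' @param baseline_psi Control PSI in percent, `[0, 100]` (recycled).
#' @param dpsi_max Maximal PSI shift in percentage points (signed, recycled).
#' @param ed50 Dose of half-maximal shift (uM, recycled).
#' @param hill_n Shape coefficient (recycled, default 1).
#' @param read_depth Expected inclusion+exclusion reads per sample (>= 1,
#'   recycled).
#' @return A tibble with one row per event.
#' @export
event_truth <- function(event_id, gene_id, event_type = "IR",
                        baseline_psi = 50, dpsi_max = 0, ed50 = 1,
                        hill_n = 1, read_depth = 100) {
  n <- length(event_id)
  out <- tibble(
    event_id = event_id,
    gene_id = rep_len(gene_id, n),
    event_type = rep_len(event_type, n),
    baseline_psi = rep_len(baseline_psi, n),
    dpsi_max = rep_len(dpsi_max, n),
    ed50 = rep_len(ed50, n),
    hill_n = rep_len(hill_n, n),
    read_depth = rep_len(read_depth, n)
  )
  if (any(!out$event_type %in% c("EX", "IR", "ALT3", "ALT5"))) {
    abort("`event_type` must be one of EX, IR, ALT3, ALT5")
  }
  if (any(out$baseline_psi < 0 | out$baseline_psi > 100)) {
    abort("`baseline_psi` must lie in [0, 100]")
  }
  if (any(out$read_depth < 1)) abort("`read_depth` must be >= 1")
  out
}
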