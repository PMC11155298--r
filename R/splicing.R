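# Percent-spliced-in quantification and differential splicing calls.
#
# PSI = 100 * inclusion / (inclusion + exclusion) per sample, reported only
# where junction coverage reaches a minimum. Differential calls combine a
# point-estimate threshold (|dPSI| > 5 percentage points) with a
# credible-interval confidence rule: replicate reads are pooled per group
# under a Beta(1, 1) prior, and the event is confident only when the central
# 95% credible interval of the PSI difference excludes zero. The reported
# `mv_dpsi_95` is the interval endpoint nearer zero (in absolute value), or
# 0 when the interval touches zero.

SPLICE_TYPES <- c("EX", "IR", "ALT3", "ALT5")

#' Per-sample PSI from junction reads
#'
#' @param events Long tibble with `event_id`, `sample_id`, `inc_reads`,
#'   `exc_reads` (extra columns pass through).
#' @param min_coverage Minimum `inc + exc` reads for a PSI value; below it
#'   PSI is `NA` (default 10).
#' @return The input with a `psi` column in percent.
#' @export
compute_psi_table <- function(events, min_coverage = 10) {
  stopifnot_cols(events, c("event_id", "sample_id", "inc_reads",
                           "exc_reads"), "events")
  if (any(events$inc_reads < 0 | events$exc_reads < 0)) {
    abort("junction read counts must be non-negative")
  }
  total <- events$inc_reads + events$exc_reads
  psi <- ifelse(total >= min_coverage, 100 * events$inc_reads / total,
                NA_real_)
  dplyr::mutate(events, psi = psi)
}

#' Differential splicing between two sample groups
#'
#' For each event, the point estimate `dpsi_point` is the difference of
#' group means of per-replicate PSI (covered replicates only). Confidence
#' comes from pooled-count Beta posteriors (`Beta(sum inc + 1, sum exc + 1)`
#' per group): `n_draws` paired posterior draws of the PSI difference give a
#' central credible interval at level `conf`; `mv_dpsi_95` is the interval
#' endpoint nearer zero when the interval excludes zero, else 0. An event is
#' significant when `|dpsi_point| > dpsi_min` and `mv_dpsi_95 > 0`.
#'
#' Events with no covered replicate in either group are skipped with a
#' message. With the same seed, swapping the two groups exactly negates
#' `dpsi_point` and the posterior draws, so `mv_dpsi_95` is preserved.
#'
#' @param events Long junction-read tibble (as from [simulate_splicing()]).
#' @param control_samples,treated_samples Sample id vectors.
#' @param n_draws Posterior draws per event (default 10000).
#' @param seed RNG seed (required).
#' @param min_coverage Per-replicate coverage threshold for PSI (default 10).
#' @param dpsi_min Point-estimate threshold in percentage points (default 5,
#'   strict inequality).
#' @param conf Credible level of the central interval (default 0.95).
#' @return Tibble: `event_id`, `gene_id`, `event_type`, `dpsi_point`,
#'   `mv_dpsi_95`, `direction`, `significant`, `n_control_covered`,
#'   `n_treated_covered`.
#' @export
diff_splicing <- function(events, control_samples, treated_samples,
                          n_draws = 10000, seed, min_coverage = 10,
                          dpsi_min = 5, conf = 0.95) {
  psi_tab <- compute_psi_table(events, min_coverage)
  grp <- function(samples) {
    dplyr::filter(psi_tab, .data$sample_id %in% samples)
  }
  sum_grp <- function(tab) {
    dplyr::summarise(
      dplyr::group_by(tab, .data$event_id),
      inc = sum(.data$inc_reads), exc = sum(.data$exc_reads),
      mean_psi = mean(.data$psi[!is.na(.data$psi)]),
      n_cov = sum(!is.na(.data$psi)), .groups = "drop"
    )
  }
  sc <- sum_grp(grp(control_samples))
  st <- sum_grp(grp(treated_samples))
  meta <- dplyr::distinct(events, .data$event_id,
                          gene_id = .data$gene_id,
                          event_type = .data$event_type)
  tab <- dplyr::inner_join(sc, st, by = "event_id",
                           suffix = c("_c", "_t"))
  skipped <- tab$event_id[tab$n_cov_c == 0 | tab$n_cov_t == 0]
  if (length(skipped)) {
    inform(sprintf("skipping %d event(s) with no covered replicate: %s",
                   length(skipped),
                   paste(head(skipped, 5), collapse = ", ")))
    tab <- tab[!tab$event_id %in% skipped, , drop = FALSE]
  }
  n_e <- nrow(tab)
  if (n_e == 0) {
    return(tibble(event_id = character(), gene_id = character(),
                  event_type = character(), dpsi_point = numeric(),
                  mv_dpsi_95 = numeric(), direction = character(),
                  significant = logical(), n_control_covered = integer(),
                  n_treated_covered = integer()))
  }
  # uniform draws assigned by a label-stable key so that swapping the group
  # roles reuses each group's own draws (exact antisymmetry under swap)
  key_c <- paste(sort(unique(control_samples)), collapse = "|")
  key_t <- paste(sort(unique(treated_samples)), collapse = "|")
  draws <- with_seed(seed, list(matrix(runif(n_e * n_draws), n_e, n_draws),
                                matrix(runif(n_e * n_draws), n_e, n_draws)))
  if (key_c <= key_t) {
    u_c <- draws[[1]]; u_t <- draws[[2]]
  } else {
    u_t <- draws[[1]]; u_c <- draws[[2]]
  }
  beta_draws <- function(u, inc, exc) {
    matrix(qbeta(as.vector(u), rep(inc + 1, ncol(u)),
                 rep(exc + 1, ncol(u))), nrow(u), ncol(u))
  }
  delta <- 100 * (beta_draws(u_t, tab$inc_t, tab$exc_t) -
                    beta_draws(u_c, tab$inc_c, tab$exc_c))
  alpha <- (1 - conf) / 2
  q_lo <- apply(delta, 1, quantile, probs = alpha, names = FALSE)
  q_hi <- apply(delta, 1, quantile, probs = 1 - alpha, names = FALSE)
  mv <- ifelse(q_lo > 0, q_lo, ifelse(q_hi < 0, -q_hi, 0))
  dpsi <- tab$mean_psi_t - tab$mean_psi_c
  out <- tibble(
    event_id = tab$event_id,
    dpsi_point = dpsi,
    mv_dpsi_95 = mv,
    direction = ifelse(dpsi < 0, "down", "up"),
    significant = abs(dpsi) > dpsi_min & mv > 0,
    n_control_covered = as.integer(tab$n_cov_c),
    n_treated_covered = as.integer(tab$n_cov_t)
  )
  dplyr::relocate(dplyr::left_join(out, meta, by = "event_id"),
                  "event_id", "gene_id", "event_type")
}

#' Differential splicing for every positive dose versus control
#'
#' @param events Long junction-read tibble with a `sample_id` column
#'   matching the design.
#' @param design Design tibble.
#' @param seed RNG seed; each dose contrast uses an offset seed.
#' @inheritParams diff_splicing
#' @return Row-bound [diff_splicing()] results with a `dose_uM` column.
#' @export
diff_splicing_by_dose <- function(events, design, n_draws = 10000, seed,
                                  min_coverage = 10, dpsi_min = 5,
                                  conf = 0.95) {
  validate_design(design)
  ctrl <- samples_at_dose(design, 0)
  doses <- setdiff(dose_levels(design), 0)
  purrr::imap_dfr(doses, function(d, i) {
    res <- diff_splicing(events, ctrl, samples_at_dose(design, d),
                         n_draws = n_draws, seed = seed + i,
                         min_coverage = min_coverage, dpsi_min = dpsi_min,
                         conf = conf)
    dplyr::mutate(res, dose_uM = d, .after = "event_type")
  })
}

#' Tally significant splicing events by dose, type and direction
#'
#' @param results Differential-splicing results carrying `dose_uM`,
#'   `event_type`, `direction`, `significant`.
#' @param doses Dose grid for the output (default: doses present in
#'   `results`).
#' @return Complete dose x event-type x direction count table (zeros
#'   included), the layout used for event-count reporting.
#' @export
tally_event_changes <- function(results, doses = NULL) {
  stopifnot_cols(results, c("dose_uM", "event_type", "direction",
                            "significant"), "results")
  doses <- doses %||% sort(unique(results$dose_uM))
  grid <- tidyr::expand_grid(dose_uM = doses,
                             event_type = SPLICE_TYPES,
                             direction = c("up", "down"))
  sig <- dplyr::filter(results, .data$significant)
  counts <- dplyr::count(sig, .data$dose_uM, .data$event_type,
                         .data$direction, name = "n")
  out <- dplyr::left_join(grid, counts,
                          by = c("dose_uM", "event_type", "direction"))
  dplyr::mutate(out, n = as.integer(tidyr::replace_na(.data$n, 0L)))
}
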