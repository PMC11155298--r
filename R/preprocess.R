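# Count preprocessing: the low-count filter, the log2(count+1) +
# per-sample median normalization that feeds dose-response modeling, the
# ANOVA/fold-change prefilter, and per-dose differential expression.

#' Drop features with low total counts
#'
#' Features whose summed raw count across all samples of the experiment is
#' below `min_total` are removed before any analysis.
#'
#' @param counts Wide counts tibble (`feature_id` + sample columns).
#' @param min_total Minimum total count to keep a feature (default 10;
#'   features with totals strictly below are dropped).
#' @return Filtered counts tibble.
#' @export
filter_low_counts <- function(counts, min_total = 10) {
  m <- as_feature_matrix(counts)
  if (any(m < 0)) abort("counts must be non-negative")
  keep <- rowSums(m) >= min_total
  if (!any(keep)) warn("all features removed by the low-count filter")
  counts[keep, , drop = FALSE]
}

#' Log2-transform and median-normalize a count matrix
#'
#' Computes `log2(count + 1)`, then shifts each sample so its median equals
#' the grand median of per-sample medians. The applied transforms are
#' recorded in the `normalization` attribute. Normalizing twice is a no-op
#' on the values.
#'
#' @param counts Wide counts tibble (or an already log-scale matrix tibble
#'   when `log2_transform = FALSE`).
#' @param log2_transform Apply `log2(x + 1)` first (default `TRUE`).
#' @return Wide tibble of normalized log2 values with a `normalization`
#'   attribute listing the applied transforms.
#' @export
normalize_matrix <- function(counts, log2_transform = TRUE) {
  m <- as_feature_matrix(counts)
  record <- character(0)
  if (log2_transform) {
    if (any(m < 0)) abort("counts must be non-negative")
    m <- log2(m + 1)
    record <- c(record, "log2(count+1)")
  }
  if (nrow(m) < 2) {
    warn("fewer than 2 features: median normalization skipped")
  } else {
    med <- apply(m, 2, median)
    target <- median(med)
    m <- sweep(m, 2, med - target)
    record <- c(record, sprintf("median-normalized to %.6g", target))
  }
  as_feature_tibble(m, attrs = list(normalization = record))
}

# vectorized one-way fixed-effects ANOVA across dose groups; returns p per
# feature. Degenerate zero-within-variance features: p = 0 if any group mean
# differs, else 1 (documented convention).
anova_p_vec <- function(m, group) {
  group <- as.factor(group)
  n <- ncol(m)
  g <- nlevels(group)
  Z <- stats::model.matrix(~ group - 1)
  ng <- colSums(Z)
  gm <- m %*% Z %*% diag(1 / ng, g)       # feature x group means
  grand <- rowMeans(m)
  ssb <- as.vector((gm - grand)^2 %*% ng)
  ssw <- rowSums((m - gm %*% t(Z))^2)
  f <- (ssb / (g - 1)) / (ssw / (n - g))
  p <- pf(f, g - 1, n - g, lower.tail = FALSE)
  tol <- 1e-12 * pmax(1, rowMeans(m^2))
  degen <- ssw <= tol
  p[degen] <- ifelse(ssb[degen] > tol[degen], 0, 1)
  unname(p)
}

# per-feature group means on the log2 scale, feature x dose-level matrix
group_means <- function(m, design) {
  doses <- dose_levels(design)
  sapply(doses, function(d) {
    rowMeans(m[, samples_at_dose(design, d), drop = FALSE])
  })
}

#' ANOVA + fold-change prefilter for dose-response modeling
#'
#' One-way fixed-effects ANOVA across dose groups on the log2 values, plus
#' the maximal absolute fold change of any positive dose group versus
#' control (computed on group means in log2 space and back-transformed).
#' A feature passes when `anova_p <= p_max` and
#' `max_abs_fold_change >= fc_min`.
#'
#' @param mat Normalized wide tibble from [normalize_matrix()].
#' @param design Design tibble.
#' @param p_max ANOVA p-value cutoff (default 0.05).
#' @param fc_min Minimal absolute fold change, linear scale (default 1.5).
#' @return Tibble: `feature_id`, `anova_p`, `max_abs_fold_change`, `passes`.
#' @export
anova_prefilter <- function(mat, design, p_max = 0.05, fc_min = 1.5) {
  validate_design(design)
  m <- as_feature_matrix(mat)[, design$sample_id, drop = FALSE]
  doses <- dose_levels(design)
  if (length(doses) < 2 || any(table(design$dose_uM) < 2)) {
    abort("prefilter needs >= 2 dose groups with >= 2 replicates each")
  }
  p <- anova_p_vec(m, design$dose_uM)
  gm <- group_means(m, design)
  lfc <- gm[, -1, drop = FALSE] - gm[, 1]
  max_fc <- 2^apply(abs(lfc), 1, max)
  tibble(
    feature_id = rownames(m),
    anova_p = p,
    max_abs_fold_change = max_fc,
    passes = p <= p_max & max_fc >= fc_min
  )
}

# vectorized Welch two-sample t-test on rows of m; returns list(p, diff)
welch_p_vec <- function(m, idx_a, idx_b) {
  na <- length(idx_a); nb <- length(idx_b)
  ma <- rowMeans(m[, idx_a, drop = FALSE])
  mb <- rowMeans(m[, idx_b, drop = FALSE])
  va <- apply(m[, idx_a, drop = FALSE], 1, var)
  vb <- apply(m[, idx_b, drop = FALSE], 1, var)
  se2 <- va / na + vb / nb
  t <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  tol <- 1e-12 * pmax(1, (abs(ma) + abs(mb))^2)
  degen <- se2 <= tol
  p[degen] <- ifelse(abs(mb - ma)[degen] > sqrt(tol[degen]), 0, 1)
  list(p = unname(p), diff = unname(mb - ma))
}

#' Differential expression for one dose versus control
#'
#' Per-feature Welch t-test on log2 values against the vehicle control,
#' Benjamini-Hochberg FDR across features within the contrast. A feature is
#' a differentially expressed gene (DEG) when `fdr < fdr_max` and its
#' absolute linear fold change exceeds `fc_min`.
#'
#' @param mat Normalized wide tibble from [normalize_matrix()].
#' @param design Design tibble.
#' @param dose The positive dose to contrast against control.
#' @param fdr_max FDR cutoff (default 0.05).
#' @param fc_min Absolute fold-change cutoff, linear scale (default 1.5;
#'   strict inequality).
#' @return Tibble: `feature_id`, `dose_uM`, `log2_fold_change`, `raw_p`,
#'   `fdr`, `is_deg`.
#' @export
differential_expression <- function(mat, design, dose, fdr_max = 0.05,
                                    fc_min = 1.5) {
  validate_design(design)
  m <- as_feature_matrix(mat)
  ctrl <- samples_at_dose(design, 0)
  trt <- samples_at_dose(design, dose)
  if (length(trt) == 0) abort(sprintf("no samples at dose %g", dose))
  for (nm in c("control", "treated")) {
    k <- if (nm == "control") length(ctrl) else length(trt)
    if (k < 2) abort(sprintf("%s group has %d replicate(s); >= 2 required",
                             nm, k))
  }
  w <- welch_p_vec(m, match(ctrl, colnames(m)), match(trt, colnames(m)))
  fdr <- p.adjust(w$p, method = "BH")
  tibble(
    feature_id = rownames(m),
    dose_uM = dose,
    log2_fold_change = w$diff,
    raw_p = w$p,
    fdr = fdr,
    is_deg = fdr < fdr_max & 2^abs(w$diff) > fc_min
  )
}

#' Per-dose DEG counts (dose-response summary table)
#'
#' Runs [differential_expression()] for every positive dose and tallies up-
#' and downregulated DEGs, the layout used for per-chemical dose-response
#' reporting.
#'
#' @inheritParams differential_expression
#' @return Tibble: `chemical`, `dose_uM`, `n_up`, `n_down`.
#' @export
deg_count_table <- function(mat, design, fdr_max = 0.05, fc_min = 1.5) {
  validate_design(design)
  doses <- setdiff(dose_levels(design), 0)
  purrr::map_dfr(doses, function(d) {
    de <- differential_expression(mat, design, d, fdr_max, fc_min)
    tibble(
      chemical = design$chemical[1],
      dose_uM = d,
      n_up = sum(de$is_deg & de$log2_fold_change > 0),
      n_down = sum(de$is_deg & de$log2_fold_change < 0)
    )
  })
}
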