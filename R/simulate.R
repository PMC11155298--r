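# Seeded synthetic dose-response experiments.
#
# Counts are negative binomial around dose-response mean curves on the log2
# scale; junction reads are Poisson totals split binomially at the trajectory
# PSI. Identical seeds give identical tables, so downstream stages are
# testable without any external data.

#' Simulate a negative-binomial count matrix from a truth table
#'
#' The count for feature i in sample j is drawn from a negative binomial with
#' mean `sf_j * 2^mu_i(dose_j)` and dispersion `nb_dispersion`
#' (variance `m + nb_dispersion * m^2`), where `mu_i` is the feature's
#' generating curve on the log2 scale.
#'
#' @param design Design tibble from [build_design()].
#' @param feature_truths Truth table from [feature_truth()] and friends.
#' @param nb_dispersion Negative binomial dispersion (> 0).
#' @param library_size_factors Per-sample multiplicative factors; `NULL`
#'   means all 1.
#' @param sf_log_sd If > 0 and no factors are given, draw log-normal factors
#'   with this log-SD (exercises the median normalization).
#' @param seed RNG seed (required).
#' @return Wide tibble: `feature_id` plus one integer column per sample.
#' @export
simulate_counts <- function(design, feature_truths, nb_dispersion = 0.05,
                            library_size_factors = NULL, sf_log_sd = 0,
                            seed) {
  validate_design(design)
  if (nb_dispersion <= 0) abort("`nb_dispersion` must be positive")
  stopifnot_cols(feature_truths,
                 c("feature_id", "curve_family", "curve_params"),
                 "feature_truths")
  if (anyDuplicated(feature_truths$feature_id)) {
    abort("one truth row per feature required")
  }
  bad <- setdiff(unique(feature_truths$curve_family), CURVE_FAMILIES)
  if (length(bad)) {
    abort(sprintf("unknown curve family: %s", paste(bad, collapse = ", ")))
  }
  n_s <- nrow(design)
  n_f <- nrow(feature_truths)
  with_seed(seed, {
    sf <- library_size_factors %||%
      (if (sf_log_sd > 0) exp(rnorm(n_s, 0, sf_log_sd)) else rep(1, n_s))
    if (length(sf) != n_s) {
      abort("`library_size_factors` must have one entry per sample")
    }
    counts <- matrix(0L, n_f, n_s,
                     dimnames = list(feature_truths$feature_id,
                                     design$sample_id))
    for (i in seq_len(n_f)) {
      mu <- eval_curve(feature_truths$curve_family[i],
                       feature_truths$curve_params[[i]], design$dose_uM)
      counts[i, ] <- rnbinom(n_s, mu = sf * 2^mu, size = 1 / nb_dispersion)
    }
    out <- as_feature_tibble(counts)
    out[-1] <- lapply(out[-1], as.integer)
    out
  })
}

#' Simulate splice-junction read counts from an event truth table
#'
#' Per event and sample, the read total is Poisson at the event's expected
#' depth; inclusion reads are binomial at the trajectory PSI, and exclusion
#' reads are the remainder. PSI trajectories that leave `[0, 100]` are
#' clipped with a warning.
#'
#' @param design Design tibble from [build_design()].
#' @param event_truths Truth table from [event_truth()].
#' @param seed RNG seed (required).
#' @return Long tibble: `event_id`, `gene_id`, `event_type`, `sample_id`,
#'   `dose_uM`, `inc_reads`, `exc_reads`.
#' @export
simulate_splicing <- function(design, event_truths, seed) {
  validate_design(design)
  grid <- tidyr::expand_grid(
    event_truths[c("event_id", "gene_id", "event_type", "baseline_psi",
                   "dpsi_max", "ed50", "hill_n", "read_depth")],
    design[c("sample_id", "dose_uM")]
  )
  psi <- event_psi(grid$baseline_psi, grid$dpsi_max, grid$ed50, grid$hill_n,
                   grid$dose_uM)
  if (any(psi < 0 | psi > 100)) {
    warn("PSI trajectory left [0, 100] for some events; clipped")
    psi <- pmin(pmax(psi, 0), 100)
  }
  with_seed(seed, {
    total <- rpois(nrow(grid), grid$read_depth)
    inc <- rbinom(nrow(grid), total, psi / 100)
    tibble(
      event_id = grid$event_id,
      gene_id = grid$gene_id,
      event_type = grid$event_type,
      sample_id = grid$sample_id,
      dose_uM = grid$dose_uM,
      inc_reads = as.integer(inc),
      exc_reads = as.integer(total - inc)
    )
  })
}

#' Random synthetic gene sets
#'
#' @param gene_ids Universe of gene ids to draw from.
#' @param n_sets Number of sets.
#' @param set_size Genes per set (recycled).
#' @param seed RNG seed (required).
#' @return Gene-set tibble: `set_name`, `description`, `genes` (list column).
#' @export
synthetic_gene_sets <- function(gene_ids, n_sets = 10, set_size = 25, seed) {
  set_size <- rep_len(set_size, n_sets)
  with_seed(seed, {
    tibble(
      set_name = sprintf("SET_%03d", seq_len(n_sets)),
      description = sprintf("synthetic gene set %d", seq_len(n_sets)),
      genes = lapply(set_size, function(k) {
        sample(gene_ids, min(k, length(gene_ids)))
      })
    )
  })
}

# default small fixture: a mixed null/responsive experiment used by
# write_fixtures() and the test helpers
default_fixture <- function(seed = 1, n_null = 40, n_hill = 20,
                            n_events = 30, top_dose = 100,
                            n_doses = 5, n_reps = 4) {
  design <- build_design(top_dose, n_doses, n_reps, "synthchem")
  truths <- dplyr::bind_rows(
    null_feature_truths(n_null, top_dose, seed = seed + 1, prefix = "gene_n"),
    random_hill_truths(n_hill, top_dose, seed = seed + 2, prefix = "gene_h")
  )
  types <- rep(c("IR", "EX", "ALT3", "ALT5"), length.out = n_events)
  events <- event_truth(
    sprintf("ev_%03d", seq_len(n_events)),
    gene_id = rep_len(truths$feature_id, n_events),
    event_type = types,
    baseline_psi = 40,
    dpsi_max = rep(c(30, 0), length.out = n_events),
    ed50 = top_dose / 30,
    read_depth = 120
  )
  sets <- synthetic_gene_sets(truths$feature_id, n_sets = 6, set_size = 15,
                              seed = seed + 3)
  list(design = design, feature_truths = truths, event_truths = events,
       gene_sets = sets)
}

#' Write a synthetic experiment to plain-text fixture files
#'
#' Emits the full file set the pipeline consumes: `counts.tsv` (wide,
#' integer), `metadata.tsv`, `events.tsv` (long junction reads),
#' `gene_sets.gmt`, and the two truth tables `feature_truth.tsv` /
#' `event_truth.tsv`. All files round-trip through the package readers.
#'
#' @param outdir Output directory (created if needed).
#' @param design,feature_truths,event_truths,gene_sets Experiment components;
#'   all `NULL` means a small default fixture is generated.
#' @param nb_dispersion Negative binomial dispersion for the counts.
#' @param seed RNG seed (required).
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_fixtures <- function(outdir, design = NULL, feature_truths = NULL,
                           event_truths = NULL, gene_sets = NULL,
                           nb_dispersion = 0.05, seed = 1) {
  if (is.null(design)) {
    fx <- default_fixture(seed)
    design <- fx$design
    feature_truths <- feature_truths %||% fx$feature_truths
    event_truths <- event_truths %||% fx$event_truths
    gene_sets <- gene_sets %||% fx$gene_sets
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) {
    abort(sprintf("cannot create fixture directory '%s'", outdir))
  }
  counts <- simulate_counts(design, feature_truths,
                            nb_dispersion = nb_dispersion, seed = seed)
  events <- simulate_splicing(design, event_truths, seed = seed + 1)
  paths <- c(
    counts = file.path(outdir, "counts.tsv"),
    metadata = file.path(outdir, "metadata.tsv"),
    events = file.path(outdir, "events.tsv"),
    gene_sets = file.path(outdir, "gene_sets.gmt"),
    feature_truth = file.path(outdir, "feature_truth.tsv"),
    event_truth = file.path(outdir, "event_truth.tsv")
  )
  readr::write_tsv(counts, paths["counts"])
  readr::write_tsv(design[c("sample_id", "chemical", "dose_uM", "replicate")],
                   paths["metadata"])
  readr::write_tsv(events[c("event_id", "gene_id", "event_type", "sample_id",
                            "inc_reads", "exc_reads")], paths["events"])
  write_gmt(gene_sets, paths["gene_sets"])
  ft <- feature_truths
  ft$curve_params <- vapply(ft$curve_params, paste, character(1),
                            collapse = ",")
  readr::write_tsv(ft, paths["feature_truth"])
  readr::write_tsv(event_truths, paths["event_truth"])
  invisible(paths)
}
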