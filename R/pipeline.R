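# End-to-end orchestration for one chemical: inputs (files or simulation)
# -> preprocessing -> per-dose differential expression -> differential
# splicing -> BMD modeling of expression and intron-retention counts ->
# pathway enrichment -> POD -> comparison tables. Every stage writes its
# TSV into the run directory as it completes, and a manifest records seeds,
# settings and file checksums.

#' Pipeline configuration with the standard thresholds
#'
#' Houses every stage threshold in one place. The defaults are the
#' conventional toxicogenomics settings: DEG rule FDR < 0.05 and |FC| > 1.5;
#' low-count filter at 10 total counts; ANOVA prefilter p <= 0.05 with
#' |FC| >= 1.5; differential splicing |dPSI| > 5 with a 95% credible
#' interval excluding zero; BMD filters fit p >= 0.1, BMDU/BMDL <= 40 and
#' in-range BMD; pathway rule Fisher p < 0.05 with >= 5 query genes; POD
#' from the 20 most sensitive pathways.
#'
#' @param out_dir Run directory (created by [run_pipeline()]).
#' @param seed Base RNG seed for the run (required; all stage seeds derive
#'   from it).
#' @param counts_path,metadata_path,events_path,gmt_path Input files; leave
#'   `NULL` when `simulate` is given.
#' @param simulate Optional list with elements `design`, `feature_truths`,
#'   `event_truths`, `gene_sets` (see the `synthetic_data` helpers); counts
#'   and junction reads are then generated under `seed`.
#' @param min_total,fdr_max,fc_min,anova_p_max,min_coverage,dpsi_min,
#'   splice_conf,n_draws,fit_p_min,ratio_max,pathway_p_max,min_genes,top_k
#'   Stage thresholds (see module functions).
#' @param nb_dispersion Dispersion used when simulating counts.
#' @param bmd BMD engine settings from [bmd_config()] (its filter settings
#'   are overridden by `fit_p_min` / `ratio_max` here).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed, counts_path = NULL,
                            metadata_path = NULL, events_path = NULL,
                            gmt_path = NULL, simulate = NULL,
                            min_total = 10, fdr_max = 0.05, fc_min = 1.5,
                            anova_p_max = 0.05, min_coverage = 10,
                            dpsi_min = 5, splice_conf = 0.95,
                            n_draws = 10000, fit_p_min = 0.1,
                            ratio_max = 40, pathway_p_max = 0.05,
                            min_genes = 5, top_k = 20,
                            nb_dispersion = 0.05, bmd = bmd_config()) {
  bmd$fit_p_min <- fit_p_min
  bmd$ratio_max <- ratio_max
  structure(list(
    out_dir = out_dir, seed = as.integer(seed), counts_path = counts_path,
    metadata_path = metadata_path, events_path = events_path,
    gmt_path = gmt_path, simulate = simulate, min_total = min_total,
    fdr_max = fdr_max, fc_min = fc_min, anova_p_max = anova_p_max,
    min_coverage = min_coverage, dpsi_min = dpsi_min,
    splice_conf = splice_conf, n_draws = n_draws, fit_p_min = fit_p_min,
    ratio_max = ratio_max, pathway_p_max = pathway_p_max,
    min_genes = min_genes, top_k = top_k, nb_dispersion = nb_dispersion,
    bmd = bmd
  ), class = "pipeline_config")
}

# serializable view of a config: thresholds and seed, no data objects
config_settings <- function(config) {
  keep <- setdiff(names(config), c("simulate"))
  out <- config[keep]
  out$simulate <- !is.null(config$simulate)
  out
}

#' Load serialized pipeline settings
#'
#' Reads a `config.json` written by [run_pipeline()] and re-applies the
#' defaults, giving a configuration with identical effective settings
#' (input data objects are not serialized).
#'
#' @param path Path to `config.json`.
#' @return A `pipeline_config` list.
#' @export
load_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(
    out_dir = raw$out_dir, seed = raw$seed,
    counts_path = raw$counts_path, metadata_path = raw$metadata_path,
    events_path = raw$events_path, gmt_path = raw$gmt_path,
    min_total = raw$min_total, fdr_max = raw$fdr_max,
    fc_min = raw$fc_min, anova_p_max = raw$anova_p_max,
    min_coverage = raw$min_coverage, dpsi_min = raw$dpsi_min,
    splice_conf = raw$splice_conf, n_draws = raw$n_draws,
    fit_p_min = raw$fit_p_min, ratio_max = raw$ratio_max,
    pathway_p_max = raw$pathway_p_max, min_genes = raw$min_genes,
    top_k = raw$top_k, nb_dispersion = raw$nb_dispersion,
    bmd = do.call(bmd_config, raw$bmd)
  )
}

# build the wide intron-retention count matrix (inclusion reads of IR
# events) and its event -> gene map
intron_counts_from_events <- function(events) {
  ir <- dplyr::filter(events, .data$event_type == "IR")
  if (nrow(ir) == 0) {
    return(list(counts = NULL, map = NULL))
  }
  wide <- tidyr::pivot_wider(
    ir[c("event_id", "sample_id", "inc_reads")],
    names_from = "sample_id", values_from = "inc_reads", values_fill = 0L
  )
  names(wide)[1] <- "feature_id"
  map <- dplyr::distinct(ir, feature_id = .data$event_id,
                         gene_id = .data$gene_id)
  list(counts = wide, map = map)
}

#' Run the full per-chemical analysis
#'
#' Executes simulate/read -> low-count filter -> normalization -> per-dose
#' DEG counts -> ANOVA prefilter -> expression BMD -> differential splicing
#' and event tallies -> intron-retention BMD (IR inclusion reads,
#' log2-transformed and median-normalized like the gene counts) -> pathway
#' enrichment and POD per modality -> modality comparison. Each stage
#' writes its TSV into `config$out_dir`; reruns with an identical
#' configuration reproduce identical files.
#'
#' @param config A [pipeline_config()] list.
#' @return Invisibly, a list with all stage tables plus `manifest`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must come from pipeline_config()")
  }
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(out, name)
    readr::write_tsv(df, path)
    files[[name]] <<- path
    df
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  res <- list()
  stage("inputs", {
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      design <- sim$design
      validate_design(design)
      counts <- simulate_counts(design, sim$feature_truths,
                                nb_dispersion = config$nb_dispersion,
                                seed = config$seed)
      events <- simulate_splicing(design, sim$event_truths,
                                  seed = config$seed + 1)
      gene_sets <- sim$gene_sets
    } else {
      design <- read_metadata_tsv(config$metadata_path %||%
                                    abort("no metadata path or simulation"))
      counts <- read_counts_tsv(config$counts_path)
      events <- dplyr::left_join(read_events_tsv(config$events_path),
                                 design[c("sample_id", "dose_uM")],
                                 by = "sample_id")
      gene_sets <- read_gmt(config$gmt_path)
    }
    res$design <- design
    res$counts <- emit(counts, "counts.tsv")
    emit(design[c("sample_id", "chemical", "dose_uM", "replicate")],
         "metadata.tsv")
    res$events <- emit(events, "events.tsv")
    res$gene_sets <- gene_sets
  })

  stage("preprocess", {
    kept <- filter_low_counts(res$counts, config$min_total)
    res$norm <- normalize_matrix(kept)
  })

  stage("differential_expression", {
    res$deg_counts <- emit(
      deg_count_table(res$norm, res$design, config$fdr_max, config$fc_min),
      "deg_counts.tsv")
  })

  stage("prefilter", {
    res$prefilter <- emit(
      anova_prefilter(res$norm, res$design, config$anova_p_max,
                      config$fc_min),
      "prefilter.tsv")
  })

  stage("bmd_expression", {
    keep <- res$prefilter$feature_id[res$prefilter$passes]
    mat <- res$norm[res$norm$feature_id %in% keep, , drop = FALSE]
    res$bmd_expression <- emit(
      run_bmd(mat, res$design, config$bmd, modality = "expression"),
      "bmd_expression.tsv")
  })

  stage("splicing", {
    res$diff_splicing <- emit(
      diff_splicing_by_dose(res$events, res$design,
                            n_draws = config$n_draws,
                            seed = config$seed + 100,
                            min_coverage = config$min_coverage,
                            dpsi_min = config$dpsi_min,
                            conf = config$splice_conf),
      "diff_splicing.tsv")
    res$event_counts <- emit(
      tally_event_changes(res$diff_splicing,
                          doses = setdiff(dose_levels(res$design), 0)),
      "event_counts.tsv")
  })

  stage("bmd_intron", {
    ir <- intron_counts_from_events(res$events)
    if (is.null(ir$counts)) {
      res$bmd_intron <- emit(res$bmd_expression[0, ], "bmd_intron.tsv")
      res$intron_map <- tibble(feature_id = character(),
                                gene_id = character())
    } else {
      kept <- filter_low_counts(ir$counts, config$min_total)
      norm <- normalize_matrix(kept)
      pre <- anova_prefilter(norm, res$design, config$anova_p_max,
                             config$fc_min)
      mat <- norm[norm$feature_id %in% pre$feature_id[pre$passes], ,
                  drop = FALSE]
      res$bmd_intron <- emit(
        run_bmd(mat, res$design, config$bmd, modality = "intron"),
        "bmd_intron.tsv")
      res$intron_map <- ir$map
      res$intron_universe <- unique(ir$map$gene_id[ir$map$feature_id %in%
                                                      norm$feature_id])
    }
  })

  stage("pathways", {
    chem <- res$design$chemical[1]
    run_side <- function(bmd_tab, map, universe, modality) {
      passing <- dplyr::filter(bmd_tab, .data$filter_status == "pass")
      gene_bmd <- aggregate_to_genes(passing, map)
      pw <- enrich_pathways(gene_bmd, res$gene_sets, universe = universe,
                            min_genes = config$min_genes,
                            p_max = config$pathway_p_max)
      pod <- derive_pod(pw, top_k = config$top_k, chemical = chem,
                        modality = modality)
      list(gene_bmd = gene_bmd, pathways = pw, pod = pod)
    }
    expr_universe <- res$norm$feature_id
    e <- run_side(res$bmd_expression, NULL, expr_universe, "expression")
    i <- run_side(res$bmd_intron, res$intron_map,
                  res$intron_universe %||% character(0), "intron")
    res$gene_bmd_expression <- e$gene_bmd
    res$gene_bmd_intron <- i$gene_bmd
    res$pathways_expression <- emit(e$pathways, "pathways_expression.tsv")
    res$pathways_intron <- emit(i$pathways, "pathways_intron.tsv")
    res$pod_summary <- emit(dplyr::bind_rows(e$pod, i$pod),
                             "pod_summary.tsv")
    res$accumulation <- emit(dplyr::bind_rows(
      dplyr::mutate(accumulation_curve(e$gene_bmd$bmd),
                    modality = "expression"),
      dplyr::mutate(accumulation_curve(i$gene_bmd$bmd),
                    modality = "intron")
    ), "accumulation.tsv")
  })

  stage("comparison", {
    cmp <- compare_modalities_and_overlaps(list(
      expression = res$pathways_expression,
      intron = res$pathways_intron
    ))
    res$upset_counts <- emit(cmp$upset_counts, "upset_counts.tsv")
    res$modality_pairs <- emit(cmp$modality_pairs, "modality_pairs.tsv")
    res$network_edges <- emit(cmp$network_edges, "network_edges.tsv")
  })

  stage("manifest", {
    jsonlite::write_json(config_settings(config),
                         file.path(out, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    manifest <- list(
      package = "bmdsplice",
      version = as.character(utils::packageVersion("bmdsplice")),
      seed = config$seed,
      chemical = res$design$chemical[1],
      outputs = lapply(files, function(p) {
        list(path = basename(p), md5 = unname(tools::md5sum(p)))
      })
    )
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    res$manifest <- manifest
  })
  invisible(res)
}

#' Consolidated per-chemical report from a completed run directory
#'
#' Reads the stage TSVs back and assembles the summary tables: DEG counts
#' per dose, significant splicing events per dose and type, POD per
#' modality, and the paired modality comparison. Missing stage files are
#' reported in `missing_sections` rather than failing.
#'
#' @param run_dir A directory written by [run_pipeline()].
#' @return List of tibbles (`deg_counts`, `event_counts`, `pod_summary`,
#'   `modality_pairs`) plus `missing_sections`; also writes
#'   `report_summary.tsv` combining DEG and event counts per dose.
#' @export
write_report <- function(run_dir) {
  if (!dir.exists(run_dir)) {
    abort(sprintf("run directory not found: '%s'", run_dir))
  }
  wanted <- c(deg_counts = "deg_counts.tsv",
              event_counts = "event_counts.tsv",
              pod_summary = "pod_summary.tsv",
              modality_pairs = "modality_pairs.tsv")
  paths <- file.path(run_dir, wanted)
  names(paths) <- names(wanted)
  have <- file.exists(paths)
  if (!any(have)) abort(sprintf("'%s' contains no pipeline outputs",
                                run_dir))
  out <- lapply(paths[have], readr::read_tsv, show_col_types = FALSE,
                progress = FALSE)
  out$missing_sections <- names(wanted)[!have]
  if (all(c("deg_counts", "event_counts") %in% names(out))) {
    ev <- dplyr::summarise(
      dplyr::group_by(out$event_counts, dose_uM = .data$dose_uM),
      n_splicing_events = sum(.data$n), .groups = "drop"
    )
    summary <- dplyr::left_join(out$deg_counts, ev, by = "dose_uM")
    readr::write_tsv(summary, file.path(run_dir, "report_summary.tsv"))
    out$report_summary <- summary
  }
  out
}
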