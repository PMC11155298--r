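# Pathway-level aggregation: gene-level BMD medians, Fisher
# over-representation of BMD-passing genes, pathway benchmark doses,
# point-of-departure derivation, accumulation curves, cross-condition
# overlap counts and the expression-versus-splicing modality comparison.

#' Aggregate feature-level BMD results to genes
#'
#' Per gene, the BMD (and BMDL, BMDU) is the median over its features'
#' values — the identity for one-feature genes. Only passing results should
#' be supplied. Features without a mapping are dropped with a message.
#'
#' @param bmd_results BMD results tibble (`filter_status == "pass"` rows).
#' @param feature_to_gene Tibble with columns `feature_id`, `gene_id`; when
#'   `NULL`, features are taken to be genes already.
#' @return Tibble: `gene_id`, `n_features`, `bmd`, `bmdl`, `bmdu`.
#' @export
aggregate_to_genes <- function(bmd_results, feature_to_gene = NULL) {
  stopifnot_cols(bmd_results, c("feature_id", "bmd", "bmdl", "bmdu"),
                 "bmd_results")
  if (is.null(feature_to_gene)) {
    feature_to_gene <- tibble(feature_id = bmd_results$feature_id,
                              gene_id = bmd_results$feature_id)
  }
  stopifnot_cols(feature_to_gene, c("feature_id", "gene_id"),
                 "feature_to_gene")
  feature_to_gene <- dplyr::distinct(feature_to_gene, .data$feature_id,
                                     .data$gene_id)
  unmapped <- setdiff(bmd_results$feature_id, feature_to_gene$feature_id)
  if (length(unmapped)) {
    inform(sprintf("dropping %d unmapped feature(s): %s", length(unmapped),
                   paste(head(unmapped, 5), collapse = ", ")))
  }
  joined <- dplyr::inner_join(bmd_results, feature_to_gene,
                              by = "feature_id")
  dplyr::summarise(
    dplyr::group_by(joined, gene_id = .data$gene_id),
    n_features = dplyr::n(),
    bmd = median(.data$bmd), bmdl = median(.data$bmdl),
    bmdu = median(.data$bmdu), .groups = "drop"
  )
}

#' Fisher over-representation of query genes in gene sets
#'
#' For each set, the 2x2 table {query in set, query outside set, set outside
#' query, neither} over the background universe is tested with a two-tailed
#' Fisher exact test. A set is significant when `p < p_max` and at least
#' `min_genes` query genes fall in it. Gene-level BMD summaries (median and
#' mean of `bmd`, `bmdl`, `bmdu` over the query genes in the set) are
#' attached from `gene_bmd`.
#'
#' @param gene_bmd Gene-level BMD table from [aggregate_to_genes()]; its
#'   `gene_id` column is the query list.
#' @param gene_sets Gene-set tibble (`set_name`, `description`, `genes`).
#' @param universe Background gene universe. Default: all genes that entered
#'   BMD analysis must be supplied by the caller; when `NULL` the union of
#'   the gene sets is used.
#' @param min_genes Minimal query genes in a set for significance
#'   (default 5).
#' @param p_max Fisher p cutoff (default 0.05, raw p as is conventional for
#'   this style of analysis; a BH-adjusted column is also emitted).
#' @return Tibble: `set_name`, `n_set`, `n_query_in_set`, `fisher_p`,
#'   `fisher_p_bh`, `median_bmd`, `median_bmdl`, `median_bmdu`, `mean_bmd`,
#'   `mean_bmdl`, `significant`.
#' @export
enrich_pathways <- function(gene_bmd, gene_sets, universe = NULL,
                            min_genes = 5, p_max = 0.05) {
  stopifnot_cols(gene_bmd, c("gene_id", "bmd", "bmdl", "bmdu"), "gene_bmd")
  stopifnot_cols(gene_sets, c("set_name", "genes"), "gene_sets")
  universe <- unique(universe %||% unlist(gene_sets$genes))
  query <- unique(gene_bmd$gene_id)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warn(sprintf("%d query gene(s) outside the universe dropped",
                 length(outside)))
    query <- intersect(query, universe)
  }
  n_u <- length(universe)
  n_q <- length(query)
  rows <- purrr::map_dfr(seq_len(nrow(gene_sets)), function(i) {
    set_genes <- intersect(gene_sets$genes[[i]], universe)
    hit <- intersect(query, set_genes)
    k <- length(hit)
    tab <- matrix(c(k, n_q - k,
                    length(set_genes) - k,
                    n_u - n_q - length(set_genes) + k), 2)
    p <- if (sum(tab) == 0) 1 else
      fisher.test(tab, alternative = "two.sided")$p.value
    in_set <- gene_bmd[gene_bmd$gene_id %in% hit, , drop = FALSE]
    tibble(
      set_name = gene_sets$set_name[i],
      n_set = length(set_genes),
      n_query_in_set = k,
      fisher_p = p,
      median_bmd = median(in_set$bmd), median_bmdl = median(in_set$bmdl),
      median_bmdu = median(in_set$bmdu),
      mean_bmd = mean(in_set$bmd), mean_bmdl = mean(in_set$bmdl)
    )
  })
  dplyr::mutate(rows,
                fisher_p_bh = p.adjust(.data$fisher_p, "BH"),
                significant = .data$fisher_p < p_max &
                  .data$n_query_in_set >= min_genes,
                .after = "fisher_p")
}

#' Derive a point of departure from pathway benchmark doses
#'
#' Pathways are ranked by ascending `median_bmd` (most sensitive first).
#' With at least `top_k` significant pathways the POD is the mean of
#' `median_bmdl` over the `top_k` most sensitive; with fewer, it falls back
#' to the median of `median_bmdl` over all significant pathways. The mean
#' over all significant pathways is reported alongside for comparison.
#'
#' @param pathways Pathway table from [enrich_pathways()] (its
#'   `significant` rows are used).
#' @param top_k Number of most sensitive pathways to average (default 20).
#' @param chemical,modality Labels carried into the summary.
#' @return One-row tibble: `chemical`, `modality`, `n_significant_pathways`,
#'   `pod_bmdl`, `rule_used`, `mean_bmdl_top`, `mean_bmdl_all`,
#'   `median_bmdl_all`.
#' @export
derive_pod <- function(pathways, top_k = 20, chemical = NA_character_,
                       modality = NA_character_) {
  stopifnot_cols(pathways, c("set_name", "median_bmd", "median_bmdl",
                             "significant"), "pathways")
  sig <- dplyr::arrange(dplyr::filter(pathways, .data$significant),
                        .data$median_bmd)
  n_sig <- nrow(sig)
  if (n_sig == 0) {
    return(tibble(chemical = chemical, modality = modality,
                  n_significant_pathways = 0L, pod_bmdl = NA_real_,
                  rule_used = "undefined", mean_bmdl_top = NA_real_,
                  mean_bmdl_all = NA_real_, median_bmdl_all = NA_real_))
  }
  mean_top <- if (n_sig >= top_k) mean(head(sig$median_bmdl, top_k)) else
    NA_real_
  mean_all <- mean(sig$median_bmdl)
  median_all <- median(sig$median_bmdl)
  if (n_sig >= top_k) {
    pod <- mean_top
    rule <- sprintf("mean_of_%d_lowest", top_k)
  } else {
    pod <- median_all
    rule <- "median_all"
  }
  tibble(chemical = chemical, modality = modality,
         n_significant_pathways = as.integer(n_sig), pod_bmdl = pod,
         rule_used = rule, mean_bmdl_top = mean_top,
         mean_bmdl_all = mean_all, median_bmdl_all = median_all)
}

#' BMD accumulation curve
#'
#' For each grid dose, the number of values at or below it — the running
#' count plotted in BMD accumulation displays. Non-decreasing and
#' right-continuous by construction.
#'
#' @param bmd_values Positive BMD values (uM).
#' @param grid Dose grid (default: sorted unique values).
#' @return Tibble: `dose_uM`, `n_accumulated`.
#' @export
accumulation_curve <- function(bmd_values, grid = NULL) {
  bmd_values <- bmd_values[is.finite(bmd_values)]
  grid <- sort(unique(grid %||% bmd_values))
  tibble(
    dose_uM = grid,
    n_accumulated = vapply(grid, function(c) sum(bmd_values <= c),
                           numeric(1))
  )
}

#' Overlaps, paired modality table and network edges across conditions
#'
#' Takes a named list of pathway tables (one per condition — e.g. per
#' chemical or per modality) and returns: exact exclusive intersection
#' counts for every non-empty combination of the significant-pathway sets
#' (upset semantics); for condition pairs named `expression` / `intron`, a
#' paired table of mean BMDs for pathways significant in both; and a
#' pathway-condition edge list weighted by median BMD, ready for external
#' network rendering.
#'
#' @param pathway_tables Named list of [enrich_pathways()] outputs (>= 2).
#' @return List of tibbles: `upset_counts` (`combination`, `degree`, `n`),
#'   `modality_pairs` (`set_name`, `expression_mean_bmd`,
#'   `intron_mean_bmd`), `network_edges` (`set_name`, `condition`,
#'   `median_bmd`).
#' @export
compare_modalities_and_overlaps <- function(pathway_tables) {
  if (is.null(names(pathway_tables)) || length(pathway_tables) < 2) {
    abort("`pathway_tables` must be a named list of length >= 2")
  }
  sets <- lapply(pathway_tables, function(tb) {
    tb$set_name[tb$significant]
  })
  nms <- names(sets)
  combos <- purrr::map_dfr(seq_len(2^length(nms) - 1), function(mask) {
    members <- nms[bitwAnd(mask, 2^(seq_along(nms) - 1)) > 0]
    inside <- Reduce(intersect, sets[members])
    outside <- unique(unlist(sets[setdiff(nms, members)]))
    tibble(combination = paste(members, collapse = "&"),
           degree = length(members),
           n = length(setdiff(inside, outside)))
  })
  combos <- dplyr::filter(combos, .data$n > 0)
  pairs <- tibble(set_name = character(), expression_mean_bmd = numeric(),
                  intron_mean_bmd = numeric())
  if (all(c("expression", "intron") %in% nms)) {
    shared <- intersect(sets[["expression"]], sets[["intron"]])
    e <- pathway_tables[["expression"]]
    i <- pathway_tables[["intron"]]
    pairs <- tibble(
      set_name = shared,
      expression_mean_bmd = e$mean_bmd[match(shared, e$set_name)],
      intron_mean_bmd = i$mean_bmd[match(shared, i$set_name)]
    )
  }
  edges <- purrr::imap_dfr(pathway_tables, function(tb, nm) {
    sig <- dplyr::filter(tb, .data$significant)
    tibble(set_name = sig$set_name, condition = nm,
           median_bmd = sig$median_bmd)
  })
  list(upset_counts = combos, modality_pairs = pairs,
       network_edges = edges)
}
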