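# shared fixture builders; everything is generated in code under fixed seeds

tiny_design <- function(top = 100, n_doses = 5, reps = 4, chem = "chem") {
  build_design(top, n_doses, reps, chem)
}

# noiseless responses on a given curve over a design
curve_data <- function(design, family, params, sd = 0, seed = 1) {
  y <- eval_curve(family, params, design$dose_uM)
  if (sd > 0) y <- y + withr::with_seed(seed, rnorm(length(y), 0, sd))
  tibble::tibble(dose = design$dose_uM, response = y)
}

# wide matrix tibble from a feature x sample matrix
wide_tibble <- function(m) {
  out <- tibble::tibble(feature_id = rownames(m))
  dplyr::bind_cols(out, tibble::as_tibble(m, .name_repair = "minimal"))
}

# a scenario where expression responds only at high doses while intron
# retention responds (PSI and counts) at low doses; used for the pipeline
# and the qualitative acceptance check
low_intron_scenario <- function(n_genes = 500, n_events = 200, seed = 42) {
  design <- build_design(1000, 9, 4, "diazinon")
  n_resp <- round(n_genes * 0.2)
  set_pool <- sprintf("g%04d", seq_len(n_genes))
  resp_genes <- set_pool[seq_len(n_resp)]
  null_genes <- setdiff(set_pool, resp_genes)
  truths <- dplyr::bind_rows(
    # responsive genes: Hill curves with high half-max doses -> high BMDs,
    # effects essentially confined to the top doses
    random_hill_truths(n_resp, 1000, k_range = c(150, 600),
                       v_range = c(1.5, 2.5), residual_sd = 0.25,
                       seed = seed + 1, prefix = "unused"),
    null_feature_truths(n_genes - n_resp, 1000, residual_sd = 0.25,
                        seed = seed + 2, prefix = "unused")
  )
  truths$feature_id <- c(resp_genes, null_genes)
  # IR events on the responsive genes with low half-max doses (~1 uM): the
  # retention reads rise at doses where expression is still flat. Stable
  # (null) IR events on other genes anchor the intron-level median
  # normalization, as the bulk of introns does in real data.
  n_ir_resp <- round(n_events * 0.25)
  n_ir_null <- round(n_events * 0.35)
  ir <- event_truth(sprintf("ir%04d", seq_len(n_ir_resp)),
                    gene_id = rep_len(resp_genes, n_ir_resp),
                    event_type = "IR", baseline_psi = 30,
                    dpsi_max = 40, ed50 = 1, hill_n = 1.5,
                    read_depth = 200)
  ir_null <- event_truth(sprintf("is%04d", seq_len(n_ir_null)),
                         gene_id = rep_len(null_genes, n_ir_null),
                         event_type = "IR", baseline_psi = 40,
                         dpsi_max = 0, read_depth = 200)
  n_rest <- n_events - n_ir_resp - n_ir_null
  null_ev <- event_truth(sprintf("nv%04d", seq_len(n_rest)),
                         gene_id = rep_len(null_genes, n_rest),
                         event_type = rep(c("EX", "ALT3", "ALT5"),
                                          length.out = n_rest),
                         baseline_psi = 50, dpsi_max = 0, read_depth = 200)
  ir <- dplyr::bind_rows(ir, ir_null)
  sets <- synthetic_gene_sets(set_pool, n_sets = 12, set_size = 40,
                              seed = seed + 3)
  # concentrate responsive genes in the first four sets so both modalities
  # enrich the same pathways
  for (i in 1:4) {
    k <- length(sets$genes[[i]])
    take <- withr::with_seed(seed + 10 + i, sample(resp_genes, 30))
    sets$genes[[i]] <- unique(c(take, sets$genes[[i]]))[seq_len(k)]
  }
  list(design = design, feature_truths = truths,
       event_truths = dplyr::bind_rows(ir, null_ev), gene_sets = sets)
}
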