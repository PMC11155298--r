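test_that("low-count filter drops features below 10 total counts", {
  des <- tiny_design(n_doses = 1, reps = 2)  # 4 samples
  m <- rbind(f1 = c(3, 3, 2, 1),   # total 9  -> dropped
             f2 = c(3, 3, 2, 2),   # total 10 -> kept
             f3 = c(3, 3, 3, 2))   # total 11 -> kept
  colnames(m) <- des$sample_id
  kept <- filter_low_counts(wide_tibble(m))
  expect_equal(kept$feature_id, c("f2", "f3"))
  expect_warning(empty <- filter_low_counts(wide_tibble(m * 0)), "removed")
  expect_equal(nrow(empty), 0L)
  # survivor count equals a brute-force tally on a random fixture
  rand <- withr::with_seed(9, matrix(rpois(200 * 4, 2.6), 200,
                                     dimnames = list(sprintf("g%03d", 1:200),
                                                     des$sample_id)))
  expect_equal(nrow(filter_low_counts(wide_tibble(rand))),
               sum(rowSums(rand) >= 10))
})

test_that("normalization is log2(count+1) with exact median alignment", {
  des <- tiny_design(n_doses = 2, reps = 2)
  m <- withr::with_seed(4, matrix(rnbinom(50 * 6, mu = 100, size = 20), 50,
                                  dimnames = list(sprintf("g%02d", 1:50),
                                                  des$sample_id)))
  norm <- normalize_matrix(wide_tibble(m))
  v <- bmdsplice:::as_feature_matrix(norm)
  meds <- apply(v, 2, median)
  expect_equal(unname(meds), rep(meds[[1]], ncol(v)), tolerance = 1e-9)
  expect_equal(attr(norm, "normalization")[1], "log2(count+1)")
  # count 0 maps to 0 before shifting
  expect_equal(log2(0 + 1), 0)
  # a sample offset by +2 in log2 space (x4 counts) is removed exactly
  m2 <- m
  m2[, 1] <- (m[, 1] + 1) * 4 - 1
  v2 <- bmdsplice:::as_feature_matrix(normalize_matrix(wide_tibble(m2)))
  expect_equal(unname(v2[, 1] - v[, 1]), rep(0, 50), tolerance = 1e-9)
  # idempotence: normalizing the normalized values changes nothing
  again <- normalize_matrix(norm, log2_transform = FALSE)
  expect_equal(bmdsplice:::as_feature_matrix(again), v, tolerance = 1e-12)
  # single-feature matrix skips median normalization with a warning
  expect_warning(normalize_matrix(wide_tibble(m[1, , drop = FALSE])),
                 "skipped")
})

test_that("ANOVA prefilter applies the F-test and fold-change conjunction", {
  des <- tiny_design(n_doses = 4, reps = 4)
  n_s <- nrow(des)
  base <- withr::with_seed(5, matrix(rnorm(30 * n_s, 7, 0.3), 30))
  rownames(base) <- sprintf("g%02d", 1:30)
  colnames(base) <- des$sample_id
  # g01: constant -> fails; g02: +10 SD shift at top dose and FC >= 1.5
  m <- base
  m["g01", ] <- 7
  m["g02", des$dose_uM == max(des$dose_uM)] <-
    m["g02", des$dose_uM == max(des$dose_uM)] + 10 * 0.3 + 0.6
  pre <- anova_prefilter(wide_tibble(m), des)
  expect_false(pre$passes[pre$feature_id == "g01"])
  expect_true(pre$passes[pre$feature_id == "g02"])
  # F-test oracle: stats::oneway.test with equal variances, per feature
  for (g in c("g02", "g05", "g17")) {
    oracle <- stats::oneway.test(m[g, ] ~ factor(des$dose_uM),
                                 var.equal = TRUE)$p.value
    expect_equal(pre$anova_p[pre$feature_id == g], oracle,
                 tolerance = 1e-10)
  }
  # significant p but fold change below 1.5 fails the conjunction
  m2 <- base
  m2["g03", ] <- 7 + 0.2 * (des$dose_uM == max(des$dose_uM))  # FC 2^0.2
  pre2 <- anova_prefilter(wide_tibble(m2), des)
  row <- pre2[pre2$feature_id == "g03", ]
  expect_lt(row$anova_p, 0.05)
  expect_lt(row$max_abs_fold_change, 1.5)
  expect_false(row$passes)
  # pass set invariant under per-sample median shifts
  shift <- withr::with_seed(6, rnorm(n_s, 0, 0.5))
  pre3 <- anova_prefilter(wide_tibble(sweep(m, 2, shift, `+`)), des)
  expect_identical(pre3$passes, pre$passes)
})

test_that("differential expression applies the FDR/fold-change DEG rule", {
  des <- tiny_design(n_doses = 2, reps = 4)
  n_s <- nrow(des)
  top <- max(des$dose_uM)
  m <- withr::with_seed(8, matrix(rnorm(500 * n_s, 7, 0.25), 500))
  rownames(m) <- sprintf("g%03d", 1:500)
  colnames(m) <- des$sample_id
  # forced detection: +2 log2 units, tiny noise
  m["g001", ] <- 7 + 2 * (des$dose_uM == top) +
    withr::with_seed(9, rnorm(n_s, 0, 0.01))
  # below-threshold fold change with overwhelming significance: FC = 1.49
  m["g002", ] <- 7 + log2(1.49) * (des$dose_uM == top) +
    withr::with_seed(10, rnorm(n_s, 0, 1e-4))
  de <- differential_expression(wide_tibble(m), des, top)
  expect_true(de$is_deg[de$feature_id == "g001"])
  expect_gt(de$log2_fold_change[de$feature_id == "g001"], 0)
  g2 <- de[de$feature_id == "g002", ]
  expect_lt(g2$fdr, 0.05)
  expect_false(g2$is_deg)
  # Welch oracle on a few features
  ctrl <- des$sample_id[des$dose_uM == 0]
  trt <- des$sample_id[des$dose_uM == top]
  for (g in c("g010", "g250")) {
    oracle <- stats::t.test(m[g, trt], m[g, ctrl])$p.value
    expect_equal(de$raw_p[de$feature_id == g], oracle, tolerance = 1e-10)
  }
  # BH invariants: fdr >= raw p, monotone after sorting by p
  expect_true(all(de$fdr >= de$raw_p - 1e-15))
  ord <- order(de$raw_p)
  expect_true(all(diff(de$fdr[ord]) >= -1e-15))
  # DEG set is a subset of |FC| > 1.5
  expect_true(all(2^abs(de$log2_fold_change[de$is_deg]) > 1.5))
  des1 <- des[!(des$dose_uM == 0 & des$replicate > 1), ]
  expect_error(differential_expression(wide_tibble(m), des1, top),
               "control")
})

test_that("per-dose DEG counts match the per-contrast results", {
  des <- tiny_design(n_doses = 3, reps = 3)
  m <- withr::with_seed(12, matrix(rnorm(80 * nrow(des), 7, 0.2), 80))
  rownames(m) <- sprintf("g%02d", 1:80)
  colnames(m) <- des$sample_id
  top <- max(des$dose_uM)
  m[1:5, des$dose_uM == top] <- m[1:5, des$dose_uM == top] + 3
  m[6:8, des$dose_uM == top] <- m[6:8, des$dose_uM == top] - 3
  tab <- deg_count_table(wide_tibble(m), des)
  expect_equal(nrow(tab), 3L)
  de_top <- differential_expression(wide_tibble(m), des, top)
  expect_equal(tab$n_up[tab$dose_uM == top],
               sum(de_top$is_deg & de_top$log2_fold_change > 0))
  expect_equal(tab$n_down[tab$dose_uM == top],
               sum(de_top$is_deg & de_top$log2_fold_change < 0))
})
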