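test_that("BMD matches the closed forms for linear and Hill curves", {
  des <- tiny_design(top = 10, n_doses = 4, reps = 2)
  # linear slope 1, sigma 2 -> BMD = 2
  f_lin <- fit_model(curve_data(des, "linear", c(0, 1)), "linear")
  expect_equal(compute_bmd(f_lin, bmr = 2)$bmd, 2, tolerance = 1e-8)
  # hill v0=0, v=4, k=10, n=1, sigma=1 -> 4d/(10+d) = 1 -> d = 10/3
  des2 <- build_design(1000, 9, 2, "x")
  f_hill <- fit_model(curve_data(des2, "hill", c(0, 4, 10, 1)), "hill",
                      seed = 2)
  expect_equal(compute_bmd(f_hill, bmr = 1)$bmd, 10 / 3, tolerance = 1e-6)
  # decreasing linear f = 10 - d, sigma 1 -> BMD = 1, direction down
  f_dec <- fit_model(curve_data(des, "linear", c(10, -1)), "linear")
  got <- compute_bmd(f_dec, bmr = 1)
  expect_equal(got$bmd, 1, tolerance = 1e-8)
  expect_equal(got$adverse_direction, "down")
  # flat fitted curve: no crossing, no BMD
  f_flat <- fit_model(tibble::tibble(dose = des$dose_uM, response = 5),
                      "linear")
  expect_true(is.na(compute_bmd(f_flat, bmr = 1)$bmd))
})

test_that("BMD is scale-equivariant in dose and shift-invariant in response", {
  base <- build_design(100, 6, 3, "x")
  params <- list(linear = c(4, 0.05), poly2 = c(4, 0.05, -2e-4),
                 hill = c(4, 2, 5, 1.5), power = c(4, 0.3, 1.3),
                 exp3 = c(4, 2, 10))
  for (fam in names(params)) {
    dat <- curve_data(base, fam, params[[fam]], sd = 0.15, seed = 11)
    fit <- fit_model(dat, fam, seed = 4)
    bmd <- compute_bmd(fit)$bmd
    # dose scale x10
    dat10 <- dat
    dat10$dose <- dat$dose * 10
    bmd10 <- compute_bmd(fit_model(dat10, fam, seed = 4))$bmd
    expect_equal(bmd10, 10 * bmd, tolerance = 1e-3)
    # response shift +3
    dat_s <- dat
    dat_s$response <- dat$response + 3
    bmd_s <- compute_bmd(fit_model(dat_s, fam, seed = 4))$bmd
    expect_equal(bmd_s, bmd, tolerance = 1e-4)
  }
})

test_that("profile bounds bracket the BMD and tighten with information", {
  des <- build_design(100, 7, 4, "x")
  dat <- curve_data(des, "hill", c(5, 2, 3, 1.5), sd = 0.25, seed = 21)
  fit <- fit_model(dat, "hill", seed = 5)
  bmd <- compute_bmd(fit)$bmd
  ci <- profile_interval(fit, bmd)
  expect_true(is.finite(ci$bmdl) && is.finite(ci$bmdu))
  expect_lte(ci$bmdl, bmd)
  expect_gte(ci$bmdu, bmd)
  # 16x replication on the same generating curve shrinks the interval
  des16 <- build_design(100, 7, 64, "x")
  dat16 <- curve_data(des16, "hill", c(5, 2, 3, 1.5), sd = 0.25, seed = 21)
  fit16 <- fit_model(dat16, "hill", seed = 5)
  ci16 <- profile_interval(fit16, compute_bmd(fit16)$bmd)
  expect_lt(log(ci16$bmdu / ci16$bmdl), log(ci$bmdu / ci$bmdl))
  # near-noiseless data: the curve is pinned, leaving only the chi-square
  # floor of sigma-hat (the 1-SD benchmark response is estimated, so its
  # relative uncertainty ~1/sqrt(2n) persists at any noise level); for
  # n = 32 and a local power of 1.5 the ratio settles near
  # (r_hi/r_lo)^(1/3) where n(log r + 1/r - 1) = qchisq(.9, 1) at r_hi/r_lo
  dat0 <- curve_data(des, "hill", c(5, 2, 3, 1.5), sd = 1e-5, seed = 22)
  fit0 <- fit_model(dat0, "hill", seed = 5)
  bmd0 <- compute_bmd(fit0)$bmd
  ci0 <- profile_interval(fit0, bmd0)
  g <- function(r) 32 * (log(r) + 1 / r - 1) - qchisq(0.90, 1)
  r_hi <- uniroot(g, c(1 + 1e-9, 10))$root
  r_lo <- uniroot(g, c(1e-3, 1 - 1e-9))$root
  expect_equal(ci0$bmdu / ci0$bmdl, (r_hi / r_lo)^(1 / 3),
               tolerance = 0.05)
  expect_lte(ci0$bmdl, bmd0)
  expect_gte(ci0$bmdu, bmd0)
})

test_that("rejection filters label each result with its first failing rule", {
  des <- build_design(1000, 9, 4, "x")
  results <- tibble::tibble(
    feature_id = sprintf("f%d", 1:5),
    bmd = c(2000, 50, 50, 50, NA),       # f1 out of range, f5 no BMD
    bmdl = c(10, 10, 10, 10, NA),
    bmdu = c(20, 20, 410, 390, NA),      # f3 ratio 41, f4 ratio 39
    fit_p = c(0.5, 0.05, 0.5, 0.5, NA)   # f2 fit p below 0.1
  )
  out <- apply_result_filters(results, des)
  expect_equal(out$filter_status,
               c("fail_range", "fail_fit_p", "fail_ratio", "pass",
                 "fail_no_bmd"))
  expect_equal(sum(out$filter_status == "pass"), 1L)
  # BMD below the lowest positive dose is also out of range
  low <- apply_result_filters(
    tibble::tibble(feature_id = "f", bmd = 0.05, bmdl = 0.02, bmdu = 0.4,
                   fit_p = 0.9), des)
  expect_equal(low$filter_status, "fail_range")
  # undefined profile bound counts as an infinite ratio
  open <- apply_result_filters(
    tibble::tibble(feature_id = "f", bmd = 50, bmdl = NA_real_,
                   bmdu = NA_real_, fit_p = 0.9), des)
  expect_equal(open$filter_status, "fail_ratio")
  # stable across reruns
  expect_identical(out, apply_result_filters(results, des))
})

test_that("run_bmd handles empty input and is deterministic", {
  des <- tiny_design(n_doses = 4, reps = 3)
  empty <- run_bmd(tibble::tibble(feature_id = character()), des)
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("feature_id", "bmd", "filter_status") %in% names(empty)))
  m <- rbind(
    g1 = eval_curve("hill", c(5, 2, 10, 2), des$dose_uM) +
      withr::with_seed(31, rnorm(nrow(des), 0, 0.2)),
    g2 = withr::with_seed(32, rnorm(nrow(des), 6, 0.2))
  )
  colnames(m) <- des$sample_id
  cfg <- bmd_config(n_starts = 6, seed = 2)
  r1 <- run_bmd(wide_tibble(m), des, cfg)
  r2 <- run_bmd(wide_tibble(m), des, cfg)
  expect_identical(r1, r2)
  expect_equal(r1$modality, rep("expression", 2))
  expect_true(is.finite(r1$bmd[r1$feature_id == "g1"]))
})
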