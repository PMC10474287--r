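test_that("binomial deviation arithmetic matches hand calculations", {
  expect_equal(binomial_deviation(200, 100), 0)
  expect_equal(binomial_deviation(100, 39), -2.2)
  expect_equal(deviation_from_vaf(100, 0.5), 0)
  # the two forms agree when vaf = k/n
  expect_equal(binomial_deviation(150, 45), deviation_from_vaf(150, 45 / 150))
  expect_error(binomial_deviation(100, 120))
})

test_that("flag rule agrees with the 2-SD deviation criterion", {
  fl <- flag_potential_mosaic(100, c(50, 39, 40))
  expect_identical(fl$flagged, c(FALSE, TRUE, FALSE))   # |40-50| = 10 = sqrt(n), not >
  expect_equal(fl$threshold_fraction, rep(0.4, 3))
  set.seed(61)
  n <- sample(50:400, 50, replace = TRUE)
  k <- rbinom(50, n, runif(50, 0.1, 0.5))
  fl2 <- flag_potential_mosaic(n, k)
  expect_identical(fl2$flagged, abs(fl2$deviation) > 2)
})

test_that("read-count correction reproduces the worked example", {
  expect_equal(correct_variant_count(52, 2, 49), 78.5)
  expect_equal(round(correct_variant_count(52, 2, 49) / 171, 2), 0.46)
  expect_equal(correct_variant_count(37), 37)
})

test_that("mosaic mixing is affine on the beta scale, not the M scale", {
  ba <- c(cg1 = 0.8, cg2 = 0.95); bu <- c(cg1 = 0.2, cg2 = 0.5)
  expect_equal(synthesize_mosaic(ba, bu, 0), bu[names(ba)])
  expect_equal(synthesize_mosaic(ba, bu, 1), ba)
  expect_equal(unname(synthesize_mosaic(ba, bu, 0.5)["cg1"]), 0.5)
  # mixing then transforming differs from mixing the M-values
  mix_beta_m <- beta_to_m(synthesize_mosaic(ba, bu, 0.5))
  mix_m <- 0.5 * beta_to_m(ba) + 0.5 * beta_to_m(bu)
  expect_gt(max(abs(mix_beta_m - mix_m)), 0.1)
  expect_error(synthesize_mosaic(ba, c(cg9 = 0.5, cg8 = 0.5), 0.5), "same site")
})

test_that("leave-2-out enumeration and mosaic counts follow the combinatorics", {
  coh <- generate_insilico_cohort(
    fx_cohort$beta, fx_cases, fx_ctrl_train, unaffected_pool = fx_ctrl_indep,
    per_combo = 10, covariates = fx_cohort$covariates, p_thresh = fx_p,
    b = 3, s = 5, seed = 17)
  expect_equal(ncol(coh$combos), choose(7, 2))      # 21
  expect_equal(nrow(coh$mosaics), 21 * 10)
  expect_true(all(coh$mosaics$d >= 0 & coh$mosaics$d <= 1))
  expect_true(all(coh$mosaics$k <= coh$mosaics$n))
  expect_true(all(coh$mosaics$score >= 0 & coh$mosaics$score <= 1))
  # every left-out case joins that combination's affected donor pool only
  expect_true(all(coh$mosaics$affected %in% c(fx_cases)))
  # scores rise with the degree of mosaicism
  expect_gt(cor(coh$mosaics$d, coh$mosaics$score, method = "spearman"), 0.8)
})

test_that("quantile bands are ordered, smoothed, and evaluable off-support", {
  set.seed(62)
  mos <- data.frame(vaf = runif(1200, 0, 0.5))
  mos$score <- plogis(8 * (mos$vaf - 0.25)) + rnorm(1200, 0, 0.05)
  band <- suppressWarnings(build_band(mos, seed = 3))  # top edge bin may be empty
  expect_true(all(band$bins$q_lo_smooth <= band$bins$q_hi_smooth + 1e-12))
  # monotone signal -> non-decreasing smoothed upper band
  expect_true(all(diff(band$bins$q_hi_smooth) > -0.02))
  # constant scores -> both bands constant at that score
  cb <- suppressWarnings(
    build_band(data.frame(vaf = runif(500, 0, 0.5), score = 0.7), seed = 1))
  expect_equal(cb$bins$q_lo_smooth, rep(0.7, nrow(cb$bins)), tolerance = 1e-8)
  expect_equal(cb$bins$q_hi_smooth, rep(0.7, nrow(cb$bins)), tolerance = 1e-8)
  expect_warning(band_at(band, 0.7), "outside band support")
  ba <- suppressWarnings(band_at(band, c(0.2, 0.7)))
  expect_true(all(ba$lower <= ba$upper))
})

test_that("adjudication separates erroneous calls from genuine mosaics", {
  coh <- generate_insilico_cohort(
    fx_cohort$beta, fx_cases, fx_ctrl_train, unaffected_pool = fx_ctrl_indep,
    per_combo = 60, covariates = fx_cohort$covariates, p_thresh = fx_p,
    b = 3, s = 5, seed = 18)
  band <- build_band(coh, seed = 4)

  # erroneous call: constitutive case (d = 1) with VAF deflated to 0.28
  # genuine mosaic: half-degree mixture with reads consistent with d = 0.5
  half <- synthesize_mosaic(fx_cohort$beta[, fx_cases[3]],
                            fx_cohort$beta[, fx_ctrl_indep[2]], 0.5)
  beta2 <- cbind(fx_cohort$beta, true_mosaic = half)
  reads <- sample_depth_and_reads(0.5, seed = 63)
  suspects <- data.frame(
    sample_id = c("case_02", "true_mosaic", "ctrl_30"),
    n = c(171, reads$n, 200),
    k = c(round(0.28 * 171), reads$k, 50))
  v <- adjudicate(suspects, beta2, coh, band)
  expect_identical(v$verdict[1], "above_95")
  expect_true(v$verdict[2] %in% c("within", "below_5"))
  expect_false(v$verdict[3] == "above_95")   # unaffected profile never above
  expect_true(all(v$ci_low <= v$mean_score & v$mean_score <= v$ci_high))
})

test_that("depth presets honour their truncation bounds", {
  r <- sample_depth_and_reads(runif(300), preset = "KMT2D", seed = 64)
  expect_true(all(r$n > 14))
  expect_equal(depth_presets$KMT2B[["min"]], 47)
})
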