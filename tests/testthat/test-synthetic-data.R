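test_that("generated betas stay strictly inside (0,1) and runs are reproducible", {
  sim1 <- simulate_cohort(cohort_config(n_sites = 200, n_signature_sites = 20,
                                        seed = 11))
  sim2 <- simulate_cohort(cohort_config(n_sites = 200, n_signature_sites = 20,
                                        seed = 11))
  expect_true(all(sim1$beta > 0 & sim1$beta < 1))
  expect_true(all(is.finite(beta_to_m(sim1$beta))))
  expect_identical(sim1$beta, sim2$beta)
  expect_identical(sim1$sample_sheet, sim2$sample_sheet)
  expect_equal(unname(sim1$truth$u[sim1$truth$control_ids]),
               rep(0, length(sim1$truth$control_ids)))
})

test_that("planted effect is recovered by the sample mean and vanishes at delta 0", {
  sim <- simulate_cohort(cohort_config(n_sites = 500, n_signature_sites = 50,
                                       n_controls = 20, n_cases = 20,
                                       n_candidates = 0, effect_delta = 4,
                                       noise_sd = 0.5, covariate_effects =
                                         c(sex = 0, age = 0, cd4t = 0, gran = 0),
                                       seed = 12))
  m <- beta_to_m(sim$beta)
  sig <- sim$truth$signature_site_ids
  sgn <- sim$truth$signature_sign[sig]
  diffs <- sgn * (rowMeans(m[sig, sim$truth$case_ids]) -
                    rowMeans(m[sig, sim$truth$control_ids]))
  se <- 0.5 * sqrt(1 / 20 + 1 / 20)    # per-site SE at noise_sd 0.5
  expect_lt(abs(mean(diffs) - 4), 3 * se / sqrt(length(sig)) + 0.05)

  null <- simulate_cohort(cohort_config(n_sites = 300, n_signature_sites = 30,
                                        n_candidates = 0, effect_delta = 0,
                                        seed = 13))
  mn <- beta_to_m(null$beta)
  tr <- c(null$truth$control_ids, null$truth$case_ids)
  res <- fit_ewas(mn[, tr], as.numeric(tr %in% null$truth$case_ids),
                  covariates = null$covariates[tr, ])
  expect_gt(min(res$p), 1e-6)
})

test_that("strong-effect EWAS recovers >= 90% of planted signature sites", {
  sim <- simulate_cohort(cohort_config(n_sites = 800, n_signature_sites = 60,
                                       n_candidates = 0, seed = 14))
  m <- beta_to_m(sim$beta)
  tr <- c(sim$truth$control_ids, sim$truth$case_ids)
  res <- fit_ewas(m[, tr], as.numeric(tr %in% sim$truth$case_ids),
                  covariates = sim$covariates[tr, ])
  sel <- select_sites(res, p_thresh = 1e-6, diff_thresh = 0.4)
  expect_gte(mean(sim$truth$signature_site_ids %in% sel), 0.9)
})

test_that("variant read counts follow Bin(n, d/2) with truncated depths", {
  truth <- fx_cohort$truth
  vo <- simulate_variant_observations(fx_cohort, seed = 21)
  expect_true(all(vo$depth > 47))
  expect_true(all(vo$variant_reads <= vo$depth))

  # k/n concentrates at 1/2 for constitutive carriers at high depth
  reads <- sample_depth_and_reads(rep(1, 400), depth_mean = 10000,
                                  depth_sd = 1, depth_min = 9000, seed = 22)
  expect_gt(mean(reads$vaf >= 0.48 & reads$vaf <= 0.52), 0.98)
  expect_lt(abs(mean(reads$vaf) - 0.5), 0.002)
  # d = 0 gives zero variant reads always
  expect_true(all(sample_depth_and_reads(rep(0, 50), seed = 23)$k == 0))
  expect_error(sample_depth_and_reads(1.2), "\\[0, 1\\]")

  # mean k/n over many draws at fixed d equals d/2 within Monte-Carlo error
  r2 <- sample_depth_and_reads(rep(0.6, 2000), preset = "KMT2B", seed = 24)
  expect_true(all(r2$n > 47))
  expect_lt(abs(mean(r2$vaf) - 0.3), 0.005)
})

test_that("erroneous-call injection deflates the reported count only", {
  vo <- simulate_variant_observations(fx_cohort, deflate = c(case_01 = 0.4),
                                      seed = 25)
  row <- vo[vo$sample_id == "case_01", ]
  expect_equal(row$variant_reads, round(row$k_true * 0.6))
  expect_true(all(vo$variant_reads[vo$sample_id != "case_01"] ==
                    vo$k_true[vo$sample_id != "case_01"]))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_signature_sites = 50, n_sites = 50), "smaller")
  expect_error(cohort_config(depth_min = 0), "depth_min")
  expect_error(cohort_config(severity_range = c(0, 1)), "severity_range")
  expect_error(cohort_config(candidate_mosaic_degrees = 2), "\\[0, 1\\]")
})
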