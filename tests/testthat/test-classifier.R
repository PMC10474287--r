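test_that("separated training classes get extreme, well-calibrated scores", {
  # wide separation and enough cases that Platt's smoothed targets
  # ((n+1)/(n+2)) allow scores above 0.9
  sep <- simulate_cohort(cohort_config(n_sites = 400, n_signature_sites = 40,
                                       n_controls = 19, n_cases = 15,
                                       n_candidates = 0, effect_delta = 6,
                                       noise_sd = 0.3, seed = 55))
  msep <- beta_to_m(sep$beta)
  fit <- episignature(msep, sep$truth$case_ids, sep$truth$control_ids,
                      covariates = sep$covariates, p_thresh = 1e-6,
                      b = 5, s = 8, seed = 5)
  sc_case <- predict(fit, msep[, sep$truth$case_ids])
  sc_ctrl <- predict(fit, msep[, sep$truth$control_ids])
  expect_true(all(sc_case > 0.9))
  expect_true(all(sc_ctrl < 0.1))
  expect_true(all(sc_case >= 0 & sc_case <= 1))
  # duplicate of a training control scores as a control
  dup <- fx_m[, fx_ctrl_train[1], drop = FALSE]
  colnames(dup) <- "dup"
  expect_lt(predict(fx_fit, dup), 0.5)
  # score order is sample order
  sc <- predict(fx_fit, fx_m[, c("case_01", "ctrl_01")])
  expect_identical(names(sc), c("case_01", "ctrl_01"))
  expect_equal(unname(sc["case_01"]), unname(predict(fx_fit, fx_m[, "case_01", drop = FALSE])))
})

test_that("scoring errors on missing sites and classification uses the 0.5 cutoff", {
  sub <- fx_m[setdiff(rownames(fx_m), fx_fit$sites[1]), ]
  expect_error(predict(fx_fit, sub), fx_fit$sites[1])
  cls <- predict(fx_fit, fx_m[, c(fx_cases[1], fx_ctrl_train[1])], type = "class")
  expect_identical(unname(cls), c(TRUE, FALSE))
})

test_that("label flip maps scores to their complement within calibration tolerance", {
  # balanced fixture so class weights match across the flip
  sim <- simulate_cohort(cohort_config(n_sites = 400, n_signature_sites = 40,
                                       n_controls = 12, n_cases = 12,
                                       n_candidates = 0, seed = 51))
  m <- beta_to_m(sim$beta)
  sites <- select_sites(fit_ewas(m[, c(sim$truth$control_ids, sim$truth$case_ids)],
                                 rep(c(0, 1), each = 12)),
                        p_thresh = 1e-6)[1:10]
  f1 <- episignature(m, sim$truth$case_ids, sim$truth$control_ids,
                     sites = sites, seed = 3)
  f2 <- episignature(m, sim$truth$control_ids, sim$truth$case_ids,
                     sites = sites, seed = 3)
  test_ids <- c(sim$truth$case_ids[1:6], sim$truth$control_ids[1:6])
  s1 <- predict(f1, m[, test_ids]); s2 <- predict(f2, m[, test_ids])
  expect_lt(max(abs(s1 - (1 - s2))), 0.05)
})

test_that("linear coefficients reproduce the decision rule", {
  w <- coef(fx_fit)
  dv <- w[1] + as.numeric(crossprod(fx_m[fx_fit$sites, c(fx_cases, fx_ctrl_train)],
                                    w[-1]))
  expect_true(all(dv[seq_along(fx_cases)] > 0))
  expect_true(all(dv[-seq_along(fx_cases)] < 0))
})

test_that("stepwise re-training recruits the allelic series and keeps initial cases", {
  traj <- retrain_stepwise(fx_m, fx_cases, fx_ctrl_train, fx_cands,
                           covariates = fx_cohort$covariates, p_thresh = fx_p,
                           b = 5, s = 8, max_iter = 6, seed = 13)
  expect_true(traj$stop_reason %in% c("fixed_point", "cycle", "max_iter"))
  for (st in traj$steps)
    expect_true(all(fx_cases %in% st$case_ids))
  expect_identical(traj$steps[[1]]$case_ids, fx_cases)
  final_cases <- traj$steps[[length(traj$steps)]]$case_ids
  expect_gt(length(final_cases), length(fx_cases))
  # recruitment is monotone in planted severity: recruited candidates have
  # higher u than never-recruited ones on average
  u <- fx_cohort$truth$u
  if (length(traj$recruited) && length(setdiff(fx_cands, traj$recruited)))
    expect_gt(mean(u[traj$recruited]), mean(u[setdiff(fx_cands, traj$recruited)]))
})

test_that("re-training with no candidates stops immediately at a fixed point", {
  traj <- retrain_stepwise(fx_m, fx_cases, fx_ctrl_train, character(0),
                           covariates = fx_cohort$covariates, p_thresh = fx_p,
                           b = 3, s = 5, seed = 2)
  expect_equal(length(traj$steps), 1L)
  expect_identical(traj$stop_reason, "fixed_point")
})

test_that("specificity evaluation rejects training overlap and computes quantiles", {
  expect_error(evaluate_specificity(fx_fit, fx_m[, c(fx_ctrl_train[1], fx_ctrl_indep)]),
               "overlap")
  ev <- evaluate_specificity(fx_fit, fx_m[, fx_ctrl_indep])
  expect_gte(ev$specificity, 0.95)
  expect_lte(ev$quantiles[1], ev$quantiles[2])
  # arithmetic: 19 low + 1 high -> 0.95
  fake <- list(scores = c(rep(0.1, 19), 0.6))
  expect_equal(mean(fake$scores < 0.5), 0.95)
})

test_that("sub-threshold rank-sum comparison aggregates families and is calibrated", {
  set.seed(52)
  # all carriers above all controls -> minimal attainable one-sided p
  v <- c(a = 0.40, b = 0.42, c = 0.45)
  ctl <- c(0.05, 0.1, 0.15, 0.2)
  p_min <- wilcox.test(v, ctl, alternative = "greater", exact = FALSE,
                       correct = TRUE)$p.value
  res <- compare_subthreshold_scores(v, ctl, q95 = 0.5)
  expect_equal(res$p.value, p_min)
  # identical distributions: mean p about 0.5 over replicates
  ps <- replicate(200, {
    compare_subthreshold_scores(setNames(runif(6), letters[1:6]), runif(10),
                                q95 = 1)$p.value
  })
  expect_lt(abs(mean(ps) - 0.5), 0.08)
  # family aggregation: two members of one family contribute one value
  fam <- c("F1", "F1", NA)
  res_f <- compare_subthreshold_scores(v, ctl, q95 = 0.5, families = fam)
  expect_equal(res_f$p.value,
               wilcox.test(c(mean(v[1:2]), v[3]), ctl, alternative = "greater",
                           exact = FALSE)$p.value)
  expect_error(compare_subthreshold_scores(v, ctl, q95 = 0.01), "empty")
})
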