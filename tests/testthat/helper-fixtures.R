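# Shared fixtures, built once per test run. Sizes are desk-scale: small
# enough for fast tests, large enough that the planted signature dominates
# noise the way a real episignature dominates an EWAS.

# Strong-effect cohort with extra controls so tests can hold some out.
fx_cohort <- simulate_cohort(cohort_config(
  n_sites = 800, n_signature_sites = 60, n_controls = 30, n_cases = 7,
  n_candidates = 10, effect_delta = 4, noise_sd = 0.5, seed = 101))
fx_m <- beta_to_m(fx_cohort$beta)
fx_ctrl_train <- fx_cohort$truth$control_ids[1:19]
fx_ctrl_indep <- fx_cohort$truth$control_ids[20:30]
fx_cases <- fx_cohort$truth$case_ids
fx_cands <- fx_cohort$truth$candidate_ids

# Thresholds matched to the fixture's 800-site scale (the genome-wide 5e-8
# default presumes ~850k tests).
fx_p <- 1e-6

fx_fit <- episignature(fx_m, fx_cases, fx_ctrl_train,
                       covariates = fx_cohort$covariates,
                       p_thresh = fx_p, b = 5, s = 8, seed = 7)

# Tiny deterministic matrix for arithmetic-level tests.
toy_matrix <- function(nr = 4, nc = 6, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(nr * nc, 0.05, 0.95), nr, nc,
              dimnames = list(sprintf("cg%02d", seq_len(nr)),
                              sprintf("s%02d", seq_len(nc))))
  m
}

# Independent greedy mRMR oracle: recomputes the score by brute force at
# every step using only mutual_info(), never the package's internals.
mrmr_oracle <- function(x, y, max_size) {
  ids <- colnames(x)
  sel <- character(0)
  while (length(sel) < max_size && length(sel) < length(ids)) {
    pool <- setdiff(ids, sel)
    score <- vapply(pool, function(f) {
      rel <- mutual_info(x[, f], y)
      red <- if (length(sel)) mean(vapply(sel, function(g)
        mutual_info(x[, f], x[, g]), numeric(1))) else 0
      rel - red
    }, numeric(1))
    sel <- c(sel, pool[which.max(score)])
  }
  sel
}
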