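#' Configuration for a synthetic EPIC-like methylation cohort
#'
#' Bundles and validates the parameters of [simulate_cohort()]. Defaults
#' describe a desk-scale cohort with the structure of a small episignature
#' study: 19 controls, 7 full-effect initial cases, and a candidate group
#' forming an allelic series of moderate-effect and mosaic carriers.
#'
#' @param n_sites Total CpG count (default 2000).
#' @param n_signature_sites Planted differentially methylated sites
#'   (default 100; must be < `n_sites`).
#' @param n_controls,n_cases,n_candidates Sample counts (defaults 19, 7,
#'   10). Candidates carry the variant with per-sample severity and mosaic
#'   degree drawn as below.
#' @param effect_delta Mean M-value shift at signature sites in a
#'   full-effect, fully constitutive case (default 4 M units; sign
#'   alternates across sites so both hyper- and hypomethylation occur).
#' @param severity_range Interval in (0, 1\] for candidate severity
#'   multipliers u (default `c(0.3, 1)`); initial cases have u = 1.
#' @param candidate_severities Optional explicit severity multipliers for
#'   the candidates (recycled), overriding the uniform draw from
#'   `severity_range`; use to plant a fixed allelic series.
#' @param candidate_mosaic_degrees Mosaic degrees d for candidates,
#'   recycled over the candidate set (default 1 = constitutive).
#' @param noise_sd Residual M-value SD (default 0.5).
#' @param covariate_effects Named numeric M-value slopes for the generated
#'   covariates `sex`, `age`, `cd4t`, `gran` (defaults small
#'   confounding-scale values).
#' @param depth_mean,depth_sd,depth_min Read-depth model for
#'   [simulate_variant_observations()] (defaults 184, 93, 47).
#' @param seed Integer master seed; all randomness fans out from it.
#' @return List of class `"cohort_config"`.
#' @export
cohort_config <- function(n_sites = 2000, n_signature_sites = 100,
                          n_controls = 19, n_cases = 7, n_candidates = 10,
                          effect_delta = 4, severity_range = c(0.3, 1),
                          candidate_severities = NULL,
                          candidate_mosaic_degrees = 1, noise_sd = 0.5,
                          covariate_effects = c(sex = 0.2, age = 0.005,
                                                cd4t = 0.5, gran = 0.5),
                          depth_mean = 184, depth_sd = 93, depth_min = 47,
                          seed = 1L) {
  cfg <- list(n_sites = n_sites, n_signature_sites = n_signature_sites,
              n_controls = n_controls, n_cases = n_cases,
              n_candidates = n_candidates, effect_delta = effect_delta,
              severity_range = severity_range,
              candidate_severities = candidate_severities,
              candidate_mosaic_degrees = candidate_mosaic_degrees,
              noise_sd = noise_sd, covariate_effects = covariate_effects,
              depth_mean = depth_mean, depth_sd = depth_sd,
              depth_min = depth_min, seed = as.integer(seed))
  with(cfg, {
    if (any(c(n_sites, n_signature_sites, n_controls, n_cases) <= 0))
      stop_episig("all cohort counts must be positive")
    if (n_candidates < 0) stop_episig("n_candidates must be >= 0")
    if (n_signature_sites >= n_sites)
      stop_episig("n_signature_sites must be smaller than n_sites")
    if (depth_min < 1) stop_episig("depth_min must be >= 1")
    if (!is.finite(effect_delta)) stop_episig("effect_delta must be finite")
    if (any(severity_range <= 0) || any(severity_range > 1) ||
        severity_range[1] > severity_range[2])
      stop_episig("severity_range must be an interval inside (0, 1]")
    if (any(candidate_mosaic_degrees < 0 | candidate_mosaic_degrees > 1))
      stop_episig("mosaic degrees must lie in [0, 1]")
    if (!is.null(candidate_severities) &&
        (any(candidate_severities <= 0) || any(candidate_severities > 1)))
      stop_episig("candidate_severities must lie in (0, 1]")
  })
  structure(cfg, class = "cohort_config")
}

#' Simulate an EPIC-like methylation cohort with a planted episignature
#'
#' Baseline per-site betas come from a three-component mixture (hypo ~0.1,
#' hemimethylated ~0.5, hyper ~0.9), matching the bimodal distribution of
#' array methylation, and are perturbed on the M scale. Carriers receive an
#' additive M-scale shift of `u_i * effect_delta` at the planted signature
#' sites (u_i = per-sample severity; sign alternating across sites),
#' covariate terms, and Gaussian noise. Mosaic carriers are produced by the
#' same beta-scale mixing rule used for in-silico mosaics
#' ([synthesize_mosaic()]): the sample's fully affected and unaffected
#' profiles are generated with shared noise and mixed with degree d.
#'
#' @param config A [cohort_config()].
#' @return List with `beta` (sites x samples matrix), `sample_sheet`
#'   (data.frame: sample_id, status in control/case_initial/candidate,
#'   sex, age, cd4t, gran, age_at_onset, onset_observed), `covariates`
#'   (numeric matrix used in the EWAS), and `truth` (signature_site_ids,
#'   per-sample severity u and mosaic degree d, control/case/candidate
#'   IDs, child seeds).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  seeds <- child_seeds(cfg$seed, 4)

  ids <- list(
    control = sprintf("ctrl_%02d", seq_len(cfg$n_controls)),
    case = sprintf("case_%02d", seq_len(cfg$n_cases)),
    cand = if (cfg$n_candidates > 0)
      sprintf("cand_%02d", seq_len(cfg$n_candidates)) else character(0))
  samples <- unlist(ids, use.names = FALSE)
  n <- length(samples)
  site_ids <- sprintf("cg%06d", seq_len(cfg$n_sites))

  with_seed(seeds[[1]], {
    comp <- sample(1:3, cfg$n_sites, replace = TRUE, prob = c(0.35, 0.3, 0.35))
    base_beta <- c(0.1, 0.5, 0.9)[comp]
    base_m <- beta_to_m(base_beta) + rnorm(cfg$n_sites, 0, 0.3)
    sig_sites <- sample(site_ids, cfg$n_signature_sites)
    sig_sign <- sample(c(-1, 1), cfg$n_signature_sites, replace = TRUE)
  })

  u <- setNames(numeric(n), samples)
  d <- setNames(numeric(n), samples)
  u[ids$case] <- 1; d[ids$case] <- 1
  if (cfg$n_candidates > 0) {
    u[ids$cand] <- if (!is.null(cfg$candidate_severities))
      rep(cfg$candidate_severities, length.out = cfg$n_candidates)
    else with_seed(seeds[[2]],
      runif(cfg$n_candidates, cfg$severity_range[1], cfg$severity_range[2]))
    d[ids$cand] <- rep(cfg$candidate_mosaic_degrees,
                       length.out = cfg$n_candidates)
  }

  with_seed(seeds[[3]], {
    sex <- sample(0:1, n, replace = TRUE)
    age <- round(runif(n, 2, 60), 1)
    cd4t <- pmin(pmax(rnorm(n, 0.15, 0.04), 0.01), 0.5)
    gran <- pmin(pmax(rnorm(n, 0.55, 0.08), 0.2), 0.9)
    covs <- cbind(sex = sex, age = age, cd4t = cd4t, gran = gran)
    rownames(covs) <- samples
    ce <- cfg$covariate_effects
    cov_term <- as.vector(covs %*% ce[colnames(covs)])

    noise <- matrix(rnorm(cfg$n_sites * n, 0, cfg$noise_sd), cfg$n_sites, n)
    m_unaff <- matrix(base_m, cfg$n_sites, n) +
      matrix(cov_term, cfg$n_sites, n, byrow = TRUE) + noise
    dimnames(m_unaff) <- list(site_ids, samples)

    shift <- outer(sig_sign * cfg$effect_delta, u[samples])
    m_aff <- m_unaff
    m_aff[sig_sites, ] <- m_aff[sig_sites, ] + shift

    beta_u <- m_to_beta(m_unaff); beta_a <- m_to_beta(m_aff)
    dmat <- matrix(d[samples], cfg$n_sites, n, byrow = TRUE)
    beta <- dmat * beta_a + (1 - dmat) * beta_u

    # Age at onset: earlier onset for stronger methylation deviation
    # (u * d as effective dose), censored when simulated onset exceeds age.
    dose <- u[samples] * d[samples]
    onset <- round(pmax(0.5, 40 * (1 - dose) + rnorm(n, 0, 4)), 1)
    carrier <- dose > 0
    onset_observed <- as.integer(carrier & onset <= age)
    age_at_onset <- ifelse(carrier, pmin(onset, age), NA)
  })

  sheet <- data.frame(
    sample_id = samples,
    status = rep(c("control", "case_initial", "candidate"),
                 c(cfg$n_controls, cfg$n_cases, cfg$n_candidates)),
    sex = sex, age = age, cd4t = cd4t, gran = gran,
    age_at_onset = age_at_onset, onset_observed = onset_observed,
    severity_u = unname(u[samples]), mosaic_d = unname(d[samples]),
    stringsAsFactors = FALSE)

  list(beta = beta, sample_sheet = sheet, covariates = covs,
       truth = list(signature_site_ids = sort(sig_sites),
                    signature_sign = setNames(sig_sign, sig_sites),
                    u = u, d = d,
                    control_ids = ids$control, case_ids = ids$case,
                    candidate_ids = ids$cand, seeds = seeds,
                    config = cfg))
}

#' Simulate per-case variant read observations
#'
#' For every carrier (initial case or candidate), draws a read depth from
#' the lower-truncated normal depth model and a variant read count
#' `k ~ Bin(n, d/2)` at the carrier's true mosaic degree d. Optionally
#' injects erroneous calls: for the named samples the *reported* count is
#' deflated by the stated fraction (emulating indel under-counting by an
#' automated pipeline) while the true count is kept in `k_true`.
#'
#' @param sim A [simulate_cohort()] result (or its `$truth`).
#' @param gene Gene label written into the table (default "GENE1").
#' @param deflate Named numeric vector: sample_id -> fraction of variant
#'   reads lost in the report (e.g. `c(cand_01 = 0.45)`).
#' @param seed Integer seed (defaults to a child of the cohort seed).
#' @return data.frame: sample_id, gene, depth, variant_reads, k_true, vaf,
#'   deviation (binomial SD), flagged.
#' @export
simulate_variant_observations <- function(sim, gene = "GENE1",
                                          deflate = NULL, seed = NULL) {
  truth <- if (!is.null(sim$truth)) sim$truth else sim
  cfg <- truth$config
  carriers <- c(truth$case_ids, truth$candidate_ids)
  d <- truth$d[carriers]
  if (any(d < 0 | d > 1)) stop_episig("mosaic degree outside [0, 1]")
  seed <- seed %||% (truth$seeds[[4]] %||% NULL)
  reads <- sample_depth_and_reads(unname(d), cfg$depth_mean, cfg$depth_sd,
                                  cfg$depth_min, seed = seed)
  k_rep <- reads$k
  if (!is.null(deflate)) {
    idx <- match(names(deflate), carriers)
    if (anyNA(idx)) stop_episig("deflate names must be carrier sample IDs")
    k_rep[idx] <- round(reads$k[idx] * (1 - deflate))
  }
  fl <- flag_potential_mosaic(reads$n, k_rep)
  data.frame(sample_id = carriers, gene = gene, depth = reads$n,
             variant_reads = k_rep, k_true = reads$k,
             vaf = k_rep / reads$n, deviation = fl$deviation,
             flagged = fl$flagged, stringsAsFactors = FALSE)
}
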