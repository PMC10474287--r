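#' Binomial-SD deviation of a variant read count
#'
#' For a heterozygous constitutive variant sequenced at depth `n`, the
#' variant read count is Bin(n, 1/2) with SD `sqrt(n)/2`. The deviation of
#' an observed count `k` from the heterozygous expectation `n/2`, in those
#' SD units, is `(k - n/2) / (sqrt(n)/2)`. Negative values mean fewer
#' variant reads than expected, as in a mosaic.
#'
#' `deviation_from_vaf()` is the equivalent for a reported variant allele
#' fraction: `(vaf - 0.5) * 2 * sqrt(n)`.
#'
#' @param n Read depth (>= 1). Vectorised.
#' @param k Variant read count, `0 <= k <= n`; fractional counts are
#'   allowed (they arise from read-count correction).
#' @return Signed deviation in binomial SD units.
#' @examples
#' binomial_deviation(171, 78.5)   # -1.07
#' binomial_deviation(166, 68)     # -2.33, "2.3 binomial SD"
#' deviation_from_vaf(129, 0.28)   # -5.00
#' @export
binomial_deviation <- function(n, k) {
  stopifnot(all(n >= 1), all(k >= 0), all(k <= n))
  (k - n / 2) / (sqrt(n) / 2)
}

#' @rdname binomial_deviation
#' @param vaf Reported variant allele fraction in \[0, 1\].
#' @export
deviation_from_vaf <- function(n, vaf) {
  stopifnot(all(n >= 1), all(vaf >= 0), all(vaf <= 1))
  (vaf - 0.5) * 2 * sqrt(n)
}

#' Flag a potential mosaic from its variant read count
#'
#' A case is flagged when the absolute difference between the observed and
#' expected variant read count exceeds 2 binomial SD, i.e.
#' `|k - n/2| > sqrt(n)`. Expressed as a variant read proportion the
#' (lower) flag threshold is `0.5 - 1/sqrt(n)`.
#'
#' @inheritParams binomial_deviation
#' @return data.frame with `n`, `k`, `deviation`, `flagged`,
#'   `threshold_fraction`.
#' @examples
#' flag_potential_mosaic(100, 39)  # flagged; threshold fraction 0.4
#' @export
flag_potential_mosaic <- function(n, k) {
  dev <- binomial_deviation(n, k)
  data.frame(n = n, k = k, deviation = dev,
             flagged = abs(k - n / 2) > sqrt(n),
             threshold_fraction = 0.5 - 1 / sqrt(n))
}

#' Correct a variant read count after read re-examination
#'
#' When manual or model-based re-examination of the reads finds additional
#' variant support, the corrected count is the called variant reads, plus
#' reads misinterpreted by the caller, plus half of the non-informative
#' reads (reads that may equally derive from either allele, assuming
#' unbiased allelic sampling).
#'
#' @param called Variant reads called by the automated pipeline.
#' @param extra_variant Reads re-identified as variant-supporting.
#' @param noninformative Reads compatible with both alleles; counted 1/2.
#' @return Corrected (possibly fractional) variant read count.
#' @examples
#' correct_variant_count(52, 2, 49)  # 78.5
#' @export
correct_variant_count <- function(called, extra_variant = 0, noninformative = 0) {
  stopifnot(all(called >= 0), all(extra_variant >= 0), all(noninformative >= 0))
  called + extra_variant + noninformative / 2
}

#' Synthesize an in-silico mosaic methylation profile
#'
#' Mixes the beta-value profile of an affected (variant-carrying) and an
#' unaffected donor in proportion to the mosaic degree `d` (the fraction of
#' affected cells): `beta = d * beta_affected + (1 - d) * beta_unaffected`,
#' elementwise on the beta scale. M-values must be recomputed from the
#' mixture — mixing is affine on beta, not on M.
#'
#' @param beta_affected,beta_unaffected Named numeric vectors (site ->
#'   beta) over the same site set.
#' @param d Mosaic degree in \[0, 1\]; 1 reproduces the affected profile.
#' @return Named beta vector of the mixture, aligned to
#'   `names(beta_affected)`.
#' @export
synthesize_mosaic <- function(beta_affected, beta_unaffected, d) {
  stopifnot(length(d) == 1, d >= 0, d <= 1)
  if (is.null(names(beta_affected)) || is.null(names(beta_unaffected)) ||
      !setequal(names(beta_affected), names(beta_unaffected)))
    stop_episig("profiles must be named over the same site set")
  bu <- beta_unaffected[names(beta_affected)]
  d * beta_affected + (1 - d) * bu
}

#' Gene-specific read-depth presets
#'
#' Truncated-normal read-depth models observed for the two studied genes:
#' mean 184, SD 93, lower truncation 47 for *KMT2B*; mean 213, SD 121,
#' lower truncation 14 for *KMT2D*.
#' @export
depth_presets <- list(
  KMT2B = c(mean = 184, sd = 93, min = 47),
  KMT2D = c(mean = 213, sd = 121, min = 14))

#' Sample a read depth and variant read count for a mosaic
#'
#' Depth `n` is drawn from a lower-truncated normal (rejection sampling,
#' rounded to integer, strictly above the truncation bound); the variant
#' read count is `k ~ Bin(n, d/2)`, modelling heterozygosity of the causal
#' variant in the affected cell fraction.
#'
#' @param d Mosaic degree(s) in \[0, 1\]; one (n, k) pair per element.
#' @param depth_mean,depth_sd,depth_min Depth model; defaults to the
#'   *KMT2B* preset. Alternatively pass `preset = "KMT2D"`.
#' @param preset Optional name in `names(depth_presets)` overriding the
#'   three depth parameters.
#' @param seed Optional integer seed.
#' @return data.frame with columns `d`, `n`, `k`, `vaf = k/n`.
#' @export
sample_depth_and_reads <- function(d, depth_mean = 184, depth_sd = 93,
                                   depth_min = 47, preset = NULL, seed = NULL) {
  if (!is.null(preset)) {
    p <- depth_presets[[match.arg(preset, names(depth_presets))]]
    depth_mean <- p["mean"]; depth_sd <- p["sd"]; depth_min <- p["min"]
  }
  if (any(d < 0 | d > 1)) stop_episig("mosaic degree d must lie in [0, 1]")
  with_seed(seed, {
    n <- vapply(seq_along(d), function(i) {
      repeat {
        x <- round(rnorm(1, depth_mean, depth_sd))
        if (x > depth_min) return(as.integer(x))
      }
    }, integer(1))
    k <- rbinom(length(d), n, d / 2)
    data.frame(d = d, n = n, k = k, vaf = k / n)
  })
}

#' Generate a scored in-silico mosaic cohort over leave-2-out classifiers
#'
#' Enumerates every way of leaving `leave_out` cases out of the training
#' case set (`choose(n_cases, leave_out)` combinations; 21 for 7 cases).
#' For each combination a classifier is fit on the reduced case set — the
#' full selection chain by default, or SVM-only when `sites` is given — and
#' the left-out cases join the affected donor pool. `per_combo` mosaics are
#' then synthesized per combination: degree `d ~ U(0, 1)`, affected and
#' unaffected donors drawn uniformly from the pools, beta profiles mixed
#' with [synthesize_mosaic()], read depth and variant count sampled with
#' [sample_depth_and_reads()], and the mixture scored by that combination's
#' classifier.
#'
#' @param beta Sites x samples beta matrix covering all donors and
#'   training samples.
#' @param training_cases,control_ids Training sample IDs.
#' @param affected_pool Additional verified-carrier IDs eligible as
#'   affected donors (the left-out cases are always added per combination).
#' @param unaffected_pool Unaffected donor IDs (no overlap with training).
#' @param leave_out Cases left out per combination (default 2).
#' @param per_combo Mosaics per combination (default 150).
#' @param sites Optional fixed site list for SVM-only training.
#' @param covariates,p_thresh,diff_thresh,b,s,cost As in [episignature()].
#' @param depth_mean,depth_sd,depth_min,preset Depth model passed to
#'   [sample_depth_and_reads()].
#' @param seed Integer seed (drives combination seeds, donors, d, reads).
#' @return Object of class `"insilico_cohort"`: `mosaics` data.frame
#'   (combo, d, affected, unaffected, n, k, vaf, score), `models` (one
#'   `"episignature"` per combination), `combos` (matrix of left-out IDs).
#' @export
generate_insilico_cohort <- function(beta, training_cases, control_ids,
                                     affected_pool = character(0),
                                     unaffected_pool,
                                     leave_out = 2, per_combo = 150,
                                     sites = NULL, covariates = NULL,
                                     p_thresh = 5e-8, diff_thresh = 0.4,
                                     b = 20, s = 15, cost = 1,
                                     depth_mean = 184, depth_sd = 93,
                                     depth_min = 47, preset = NULL,
                                     seed = NULL) {
  training_cases <- as.character(training_cases)
  if (length(training_cases) < leave_out + 2)
    stop_episig("need at least leave_out + 2 training cases")
  if (length(unaffected_pool) < 1) stop_episig("unaffected pool is empty")
  combos <- combn(training_cases, leave_out)
  n_combo <- ncol(combos)
  seeds <- child_seeds(seed, n_combo + 1)
  m_all <- beta_to_m(beta)

  models <- vector("list", n_combo)
  rows <- vector("list", n_combo)
  for (ci in seq_len(n_combo)) {
    left_out <- combos[, ci]
    reduced <- setdiff(training_cases, left_out)
    models[[ci]] <- episignature(m_all, reduced, control_ids,
                                 covariates = covariates, p_thresh = p_thresh,
                                 diff_thresh = diff_thresh, b = b, s = s,
                                 sites = sites, cost = cost,
                                 seed = seeds[[ci]])
    pool_a <- union(left_out, affected_pool)
    rows[[ci]] <- with_seed(seeds[[ci]], {
      dd <- runif(per_combo)
      don_a <- sample(pool_a, per_combo, replace = TRUE)
      don_u <- sample(unaffected_pool, per_combo, replace = TRUE)
      reads <- sample_depth_and_reads(dd, depth_mean, depth_sd, depth_min,
                                      preset = preset)
      msites <- models[[ci]]$sites
      mixed <- vapply(seq_len(per_combo), function(j)
        beta_to_m(synthesize_mosaic(beta[msites, don_a[j]],
                                    beta[msites, don_u[j]], dd[j])),
        numeric(length(msites)))
      mixed <- matrix(mixed, nrow = length(msites),
                      dimnames = list(msites, sprintf("mosaic_%d_%d", ci,
                                                      seq_len(per_combo))))
      sc <- predict(models[[ci]], mixed)
      data.frame(combo = ci, d = dd, affected = don_a, unaffected = don_u,
                 n = reads$n, k = reads$k, vaf = reads$vaf,
                 score = as.numeric(sc), stringsAsFactors = FALSE)
    })
  }
  structure(list(mosaics = do.call(rbind, rows), models = models,
                 combos = combos, per_combo = per_combo, seed = seed),
            class = "insilico_cohort")
}

#' @export
print.insilico_cohort <- function(x, ...) {
  cat(sprintf("In-silico mosaic cohort: %d combinations x %d mosaics = %d scored mixtures\n",
              ncol(x$combos), x$per_combo, nrow(x$mosaics)))
  invisible(x)
}

#' Loess-smoothed score quantile bands over variant read fraction
#'
#' Bins up to `n_subsample` randomly selected in-silico mosaics into
#' fixed-width bins of relative variant read count (k/n) on \[0, 0.5\],
#' computes the requested score quantiles per occupied bin, and smooths the
#' binned quantiles against the bin centres with loess. The smoothed lower
#' band is clipped to never exceed the upper band.
#'
#' @param mosaics data.frame with columns `vaf` and `score` (e.g.
#'   `$mosaics` of an [generate_insilico_cohort()] result).
#' @param bin_width Bin width on the variant-read-fraction axis
#'   (default 0.025).
#' @param quantiles Lower/upper quantile pair (default 5th and 95th).
#' @param n_subsample Mosaics used for the band (default 3000; all if
#'   fewer).
#' @param span,degree Loess parameters (defaults 0.75, 2).
#' @param seed Seed for the subsample.
#' @return Object of class `"quantile_band"`: data.frame `bins`
#'   (bin_center, n, q_lo, q_hi, q_lo_smooth, q_hi_smooth) plus the
#'   parameters; evaluate at arbitrary fractions with [band_at()].
#' @export
build_band <- function(mosaics, bin_width = 0.025, quantiles = c(0.05, 0.95),
                       n_subsample = 3000, span = 0.75, degree = 2,
                       seed = NULL) {
  if (inherits(mosaics, "insilico_cohort")) mosaics <- mosaics$mosaics
  stopifnot(all(c("vaf", "score") %in% names(mosaics)),
            bin_width > 0, length(quantiles) == 2)
  df <- with_seed(seed, {
    if (nrow(mosaics) > n_subsample)
      mosaics[sample.int(nrow(mosaics), n_subsample), ] else mosaics
  })
  edges <- seq(0, 0.5 + bin_width, by = bin_width)
  bin <- cut(pmin(df$vaf, 0.5), edges, include.lowest = TRUE, right = FALSE)
  occupied <- levels(bin)[tabulate(bin, nbins = nlevels(bin)) > 0]
  if (length(occupied) < nlevels(bin))
    warning(sprintf("%d empty bin(s) skipped", nlevels(bin) - length(occupied)))
  centers <- (edges[-length(edges)] + edges[-1]) / 2
  tab <- do.call(rbind, lapply(which(levels(bin) %in% occupied), function(i) {
    sc <- df$score[as.integer(bin) == i]
    data.frame(bin_center = centers[i], n = length(sc),
               q_lo = quantile(sc, quantiles[1], type = 7, names = FALSE),
               q_hi = quantile(sc, quantiles[2], type = 7, names = FALSE))
  }))
  fit_lo <- loess(q_lo ~ bin_center, data = tab, span = span, degree = degree)
  fit_hi <- loess(q_hi ~ bin_center, data = tab, span = span, degree = degree)
  tab$q_hi_smooth <- predict(fit_hi, tab$bin_center)
  tab$q_lo_smooth <- pmin(predict(fit_lo, tab$bin_center), tab$q_hi_smooth)
  structure(list(bins = tab, bin_width = bin_width, quantiles = quantiles,
                 span = span, degree = degree,
                 fit_lo = fit_lo, fit_hi = fit_hi), class = "quantile_band")
}

#' Evaluate a quantile band at given variant read fractions
#'
#' Linear interpolation of the smoothed band between bin centres; fractions
#' outside the band support are evaluated at the nearest endpoint with a
#' warning.
#'
#' @param band A `"quantile_band"`.
#' @param vaf Variant read fraction(s).
#' @return data.frame with `vaf`, `lower`, `upper`.
#' @export
band_at <- function(band, vaf) {
  stopifnot(inherits(band, "quantile_band"))
  rng <- range(band$bins$bin_center)
  if (any(vaf < rng[1] | vaf > rng[2]))
    warning("fraction outside band support; evaluated at nearest band endpoint")
  v <- pmin(pmax(vaf, rng[1]), rng[2])
  lo <- approx(band$bins$bin_center, band$bins$q_lo_smooth, xout = v,
               rule = 2)$y
  hi <- approx(band$bins$bin_center, band$bins$q_hi_smooth, xout = v,
               rule = 2)$y
  data.frame(vaf = vaf, lower = pmin(lo, hi), upper = hi)
}

#' @export
print.quantile_band <- function(x, ...) {
  cat(sprintf("Score quantile band: %d occupied bin(s) of width %.3f, quantiles %.0f%%/%.0f%%, loess span %.2f\n",
              nrow(x$bins), x$bin_width, 100 * x$quantiles[1],
              100 * x$quantiles[2], x$span))
  invisible(x)
}

#' Plot an in-silico mosaic band with suspects
#'
#' Score versus variant read fraction for the synthesized mosaics, the
#' smoothed quantile band (dashed), and optionally adjudicated suspects
#' with their 95% confidence intervals.
#'
#' @param x A `"quantile_band"`.
#' @param mosaics Optional mosaic data.frame to show as background points.
#' @param verdicts Optional [adjudicate()] result to overlay.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.quantile_band <- function(x, mosaics = NULL, verdicts = NULL, ...) {
  if (inherits(mosaics, "insilico_cohort")) mosaics <- mosaics$mosaics
  graphics::plot(NA, xlim = c(0, 0.5), ylim = c(0, 1),
                 xlab = "relative variant read count",
                 ylab = "SVM probability score", ...)
  if (!is.null(mosaics))
    graphics::points(mosaics$vaf, mosaics$score, col = "grey70", pch = 16,
                     cex = 0.4)
  graphics::lines(x$bins$bin_center, x$bins$q_lo_smooth, lty = 2)
  graphics::lines(x$bins$bin_center, x$bins$q_hi_smooth, lty = 2)
  if (!is.null(verdicts)) {
    graphics::arrows(verdicts$vaf, verdicts$ci_low, verdicts$vaf,
                     verdicts$ci_high, angle = 90, code = 3, length = 0.03,
                     col = "red")
    graphics::points(verdicts$vaf, verdicts$mean_score, col = "red", pch = 16)
  }
  invisible(x)
}

#' Adjudicate suspected mosaics against the in-silico band
#'
#' Scores each suspect with every leave-2-out classifier of the ensemble,
#' summarises the scores as mean and 95% t-based confidence interval
#' (mean +/- t(0.975, m-1) * SD / sqrt(m) over the m classifiers), and
#' places the mean relative to the smoothed band at the suspect's variant
#' read fraction. Suspects above the 95th-percentile band score higher than
#' genuine mosaics with that read fraction plausibly could — the hallmark
#' of an erroneous mosaic call (e.g. indel under-counting) in a
#' constitutive carrier.
#'
#' @param suspects data.frame with `sample_id`, `n` (depth), `k` (variant
#'   reads) — or `vaf` directly.
#' @param beta Sites x samples beta matrix containing the suspects.
#' @param cohort An `"insilico_cohort"` (supplies the classifier ensemble).
#' @param band A `"quantile_band"` built from the same cohort.
#' @return data.frame of class `"mosaic_verdicts"`: `sample_id`, `vaf`,
#'   `deviation`, `mean_score`, `ci_low`, `ci_high`, `verdict` in
#'   `c("above_95", "within", "below_5")`.
#' @export
adjudicate <- function(suspects, beta, cohort, band) {
  stopifnot(inherits(cohort, "insilico_cohort"), inherits(band, "quantile_band"))
  if (!"vaf" %in% names(suspects)) suspects$vaf <- suspects$k / suspects$n
  dev <- if (all(c("n", "k") %in% names(suspects)))
    binomial_deviation(suspects$n, suspects$k)
  else deviation_from_vaf(suspects$n, suspects$vaf)
  m_all <- beta_to_m(beta)
  mm <- length(cohort$models)
  scores <- vapply(cohort$models, function(mod)
    as.numeric(predict(mod, m_all[, suspects$sample_id, drop = FALSE])),
    numeric(nrow(suspects)))
  scores <- matrix(scores, nrow = nrow(suspects))
  mean_sc <- rowMeans(scores)
  half <- qt(0.975, df = mm - 1) * apply(scores, 1, sd) / sqrt(mm)
  bnd <- band_at(band, suspects$vaf)
  verdict <- ifelse(mean_sc > bnd$upper, "above_95",
                    ifelse(mean_sc < bnd$lower, "below_5", "within"))
  out <- data.frame(sample_id = suspects$sample_id, vaf = suspects$vaf,
                    deviation = dev, mean_score = mean_sc,
                    ci_low = mean_sc - half, ci_high = mean_sc + half,
                    band_lower = bnd$lower, band_upper = bnd$upper,
                    verdict = verdict, stringsAsFactors = FALSE)
  class(out) <- c("mosaic_verdicts", "data.frame")
  out
}
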