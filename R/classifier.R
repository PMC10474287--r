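#' Fit an episignature classifier
#'
#' The core fitting function. Starting from an M-value matrix and the case
#' and control sample IDs it runs the full selection chain:
#' covariate-adjusted EWAS ([fit_ewas()]), dual-threshold site selection
#' ([select_sites()]), bootstrap-ensemble mRMR compression
#' ([mrmr_ensemble_bootstrap()]), and finally a linear-kernel support
#' vector machine with Platt probability calibration on the compressed site
#' set. The returned object scores new samples with [predict.episignature()]
#' (probabilities in \[0, 1\]; classification at score >= 0.5).
#'
#' Class imbalance (typically ~7 cases vs ~19 controls) is handled by
#' inverse-frequency class weights; set `class_weights = FALSE` to disable.
#'
#' @param m Sites x samples M-value matrix.
#' @param case_ids,control_ids Character vectors of training sample IDs
#'   (>= 2 each, disjoint).
#' @param covariates Optional per-sample covariate matrix (rownames =
#'   sample IDs) used in the EWAS step.
#' @param p_thresh,diff_thresh EWAS selection thresholds ([select_sites()]).
#' @param b,s Bootstrap count and per-bootstrap solution length for the
#'   mRMR ensemble.
#' @param sites Optional fixed site list: skips EWAS + mRMR and trains the
#'   SVM directly on these sites.
#' @param cost SVM cost parameter C (default 1).
#' @param class_weights Inverse-frequency class weights (default `TRUE`).
#' @param cross Folds for the recorded cross-validated accuracy (default
#'   10, reduced with a warning when there are fewer samples than folds).
#' @param seed Integer seed controlling the mRMR bootstraps and the Platt
#'   calibration folds.
#' @param stage Training-stage index recorded in the model (0 = initial
#'   training, k = k-th re-training).
#' @return Object of class `"episignature"`; see
#'   [predict.episignature()], [coef.episignature()],
#'   [summary.episignature()].
#' @examples
#' sim <- simulate_cohort(cohort_config(n_sites = 300, n_signature_sites = 20,
#'                                      n_candidates = 0, seed = 7))
#' m <- beta_to_m(sim$beta)
#' fit <- episignature(m, case_ids = sim$truth$case_ids,
#'                     control_ids = sim$truth$control_ids,
#'                     covariates = sim$covariates, p_thresh = 1e-5,
#'                     b = 5, s = 5, seed = 7)
#' predict(fit, m[, sim$truth$control_ids[1:3]])
#' @export
episignature <- function(m, case_ids, control_ids, covariates = NULL,
                         p_thresh = 5e-8, diff_thresh = 0.4,
                         b = 20, s = 15, sites = NULL, cost = 1,
                         class_weights = TRUE, cross = 10, seed = NULL,
                         stage = 0L) {
  assert_matrix_like(m, "M-value matrix")
  case_ids <- as.character(case_ids); control_ids <- as.character(control_ids)
  if (length(intersect(case_ids, control_ids)))
    stop_episig("case and control IDs overlap")
  missing <- setdiff(c(case_ids, control_ids), colnames(m))
  if (length(missing))
    stop_episig("training sample(s) absent from matrix: %s",
                paste(missing, collapse = ", "))
  if (length(case_ids) < 2 || length(control_ids) < 2)
    stop_episig("need at least 2 cases and 2 controls")

  train_ids <- c(control_ids, case_ids)
  y <- c(rep(0, length(control_ids)), rep(1, length(case_ids)))
  ewas <- NULL; selection <- NULL

  if (is.null(sites)) {
    covs <- if (!is.null(covariates)) as.matrix(covariates)[train_ids, , drop = FALSE]
    ewas <- fit_ewas(m[, train_ids, drop = FALSE], y, covariates = covs)
    primary <- select_sites(ewas, p_thresh = p_thresh, diff_thresh = diff_thresh)
    if (length(primary) == 0)
      stop_episig("empty signature: EWAS selected no site",
                  class = "episig_empty_signature")
    prio <- ewas$p[match(primary, ewas$site_id)]
    selection <- mrmr_ensemble_bootstrap(
      t(m[primary, train_ids, drop = FALSE]), y, b = b, s = s,
      seed = seed, priority = prio)
    sites <- selection$union
  } else {
    sites <- as.character(sites)
    miss <- setdiff(sites, rownames(m))
    if (length(miss))
      stop_episig("fixed site(s) absent from matrix: %s", paste(miss, collapse = ", "))
  }

  xt <- t(m[sites, train_ids, drop = FALSE])
  yf <- factor(ifelse(y == 1, "case", "control"), levels = c("control", "case"))
  cw <- if (isTRUE(class_weights)) {
    tb <- table(yf); setNames(as.numeric(sum(tb) / (2 * tb)), names(tb))
  } else NULL
  n_tr <- length(train_ids)
  if (cross > n_tr) {
    warning(sprintf("reducing cross-validation folds from %d to %d (sample count)",
                    cross, n_tr))
    cross <- n_tr
  }
  svm_fit <- with_seed(seed, e1071::svm(
    x = xt, y = yf, kernel = "linear", cost = cost, scale = FALSE,
    probability = TRUE, cross = cross, class.weights = cw))

  structure(list(
    sites = sites, svm = svm_fit,
    case_ids = case_ids, control_ids = control_ids,
    cost = cost, class_weights = cw, cv_accuracy = svm_fit$tot.accuracy / 100,
    ewas = ewas, selection = selection, stage = as.integer(stage),
    seed = seed,
    call = match.call()), class = "episignature")
}

#' Score samples with an episignature classifier
#'
#' @param object An `"episignature"` model.
#' @param newdata Sites x samples M-value matrix containing all model sites,
#'   or a named numeric vector for a single sample.
#' @param type `"score"` (Platt probability of the case class, default) or
#'   `"class"` (`score >= 0.5`).
#' @param ... Unused.
#' @return Named numeric vector of scores in \[0, 1\] (or logical for
#'   `type = "class"`), one per sample, in input order.
#' @export
predict.episignature <- function(object, newdata, type = c("score", "class"), ...) {
  type <- match.arg(type)
  if (is.vector(newdata)) newdata <- matrix(newdata, ncol = 1,
                                            dimnames = list(names(newdata), "sample1"))
  miss <- setdiff(object$sites, rownames(newdata))
  if (length(miss))
    stop_episig("missing model site(s) in newdata: %s", paste(miss, collapse = ", "))
  x <- t(newdata[object$sites, , drop = FALSE])
  pr <- predict(object$svm, x, probability = TRUE)
  sc <- attr(pr, "probabilities")[, "case"]
  sc <- setNames(as.numeric(sc), colnames(newdata))
  if (type == "class") sc >= 0.5 else sc
}

#' Linear weights of the episignature SVM
#'
#' @param object An `"episignature"` model.
#' @param ... Unused.
#' @return Named vector of per-site weights of the linear decision function
#'   with an `"(Intercept)"` first element, such that
#'   `decision = intercept + sum(w * M_sites)` (positive towards the case
#'   class).
#' @export
coef.episignature <- function(object, ...) {
  w <- drop(crossprod(object$svm$coefs, object$svm$SV))
  int <- -object$svm$rho
  # e1071 orients the decision value towards the first-seen class; flip
  # when that class is "control" so positive always means case.
  dv <- attr(predict(object$svm, object$svm$SV[1, , drop = FALSE],
                     decision.values = TRUE), "decision.values")
  if (startsWith(colnames(dv), "control")) { w <- -w; int <- -int }
  c("(Intercept)" = int, w)
}

#' @export
print.episignature <- function(x, ...) {
  cat(sprintf("Episignature classifier (stage %d)\n", x$stage))
  cat(sprintf("  sites: %d | cases: %d | controls: %d | cost C = %g\n",
              length(x$sites), length(x$case_ids), length(x$control_ids), x$cost))
  cat(sprintf("  10-fold CV accuracy: %.3f\n", x$cv_accuracy))
  invisible(x)
}

#' @export
summary.episignature <- function(object, ...) {
  cat(sprintf("Episignature classifier, training stage %d\n", object$stage))
  cat(sprintf("Sites (%d): %s%s\n", length(object$sites),
              paste(head(object$sites, 8), collapse = ", "),
              if (length(object$sites) > 8) ", ..." else ""))
  if (!is.null(object$selection))
    cat(sprintf("mRMR ensemble: b = %d, s = %d, union bound %d\n",
                object$selection$b, object$selection$s,
                object$selection$b * object$selection$s))
  cat(sprintf("Training: %d cases vs %d controls, CV accuracy %.3f\n",
              length(object$case_ids), length(object$control_ids),
              object$cv_accuracy))
  invisible(object)
}

#' Stepwise re-training of an episignature classifier
#'
#' Starts from the unambiguous initial case set, scores every candidate,
#' recruits candidates with score >= `threshold` into the case set, and
#' refits. By default every step re-runs the full chain (EWAS, site
#' selection, mRMR, SVM) on the enlarged case set; with `fixed_sites` only
#' the SVM is refit. Iteration stops when the case set reaches a fixed
#' point, revisits a previous case set (cycle), or hits `max_iter`. The
#' initial cases are retained in every step's case set by construction.
#'
#' @inheritParams episignature
#' @param initial_cases Unambiguous case IDs (always kept).
#' @param candidates Candidate sample IDs to score and possibly recruit
#'   (must be disjoint from `control_ids`).
#' @param threshold Recruitment score threshold (default 0.5).
#' @param max_iter Maximum number of training stages (default 10).
#' @param fixed_sites Optional fixed site list (skip per-step re-selection).
#' @return Object of class `"retrain_trajectory"`: list with `steps` (each
#'   holding `case_ids`, `scores` over candidates, `model`), `stop_reason`
#'   in `c("fixed_point", "cycle", "max_iter")`, `final` (last model),
#'   `recruited` (candidates in the final case set).
#' @export
retrain_stepwise <- function(m, initial_cases, control_ids, candidates,
                             covariates = NULL, threshold = 0.5,
                             max_iter = 10, fixed_sites = NULL,
                             p_thresh = 5e-8, diff_thresh = 0.4,
                             b = 20, s = 15, cost = 1, seed = NULL, ...) {
  initial_cases <- as.character(initial_cases)
  candidates <- setdiff(as.character(candidates), initial_cases)
  if (length(intersect(candidates, control_ids)))
    stop_episig("candidates must be disjoint from controls")
  seeds <- child_seeds(seed, max_iter + 1)

  steps <- list()
  seen <- character(0)
  cases <- initial_cases
  stop_reason <- "max_iter"
  for (it in seq_len(max_iter + 1)) {
    key <- paste(sort(cases), collapse = "|")
    model <- episignature(m, cases, control_ids, covariates = covariates,
                          p_thresh = p_thresh, diff_thresh = diff_thresh,
                          b = b, s = s, sites = fixed_sites, cost = cost,
                          seed = seeds[[it]], stage = it - 1L, ...)
    scores <- if (length(candidates))
      predict(model, m[, candidates, drop = FALSE]) else numeric(0)
    steps[[it]] <- list(case_ids = cases, scores = scores, model = model)
    nxt <- union(initial_cases, candidates[scores >= threshold])
    nxt_key <- paste(sort(nxt), collapse = "|")
    if (identical(nxt_key, key)) { stop_reason <- "fixed_point"; break }
    if (nxt_key %in% seen) { stop_reason <- "cycle"; break }
    if (it == max_iter + 1) { stop_reason <- "max_iter"; break }
    seen <- c(seen, key)
    cases <- nxt
  }
  final <- steps[[length(steps)]]$model
  structure(list(steps = steps, stop_reason = stop_reason, final = final,
                 initial_cases = initial_cases,
                 recruited = setdiff(steps[[length(steps)]]$case_ids,
                                     initial_cases),
                 threshold = threshold), class = "retrain_trajectory")
}

#' @export
print.retrain_trajectory <- function(x, ...) {
  cat(sprintf("Stepwise re-training: %d stage(s), stop reason '%s'\n",
              length(x$steps), x$stop_reason))
  for (i in seq_along(x$steps))
    cat(sprintf("  stage %d: %d cases, %d site(s), %d candidate(s) >= %.2f\n",
                i - 1, length(x$steps[[i]]$case_ids),
                length(x$steps[[i]]$model$sites),
                sum(x$steps[[i]]$scores >= x$threshold), x$threshold))
  invisible(x)
}

#' Specificity and score quantiles on independent controls
#'
#' @param model An `"episignature"` model.
#' @param m Sites x samples M-value matrix of independent controls; the
#'   sample set must be disjoint from every training sample of the model.
#' @param quantiles Score quantiles to report (default 50th and 95th,
#'   empirical type-7).
#' @return List with `specificity` (fraction scoring < 0.5), `quantiles`
#'   (named vector), `scores`.
#' @export
evaluate_specificity <- function(model, m, quantiles = c(0.5, 0.95)) {
  overlap <- intersect(colnames(m), c(model$case_ids, model$control_ids))
  if (length(overlap))
    stop_episig("independent controls overlap training samples: %s",
                paste(overlap, collapse = ", "))
  sc <- predict(model, m)
  list(specificity = mean(sc < 0.5),
       quantiles = quantile(sc, quantiles, type = 7),
       scores = sc)
}

#' Classifier performance as a function of episignature length
#'
#' Sweeps the mRMR ensemble parameters over `b_range` x `s_range`, fitting
#' one classifier per configuration, and summarises performance as a
#' function of the resulting episignature length k: specificity on
#' independent controls and pseudo-sensitivity, defined as the number of
#' candidates verified positive (score >= 0.5) divided by the maximum such
#' number over all configurations. Metrics are then averaged per realised
#' k, and a plateau onset is located for each metric: the smallest k whose
#' window of `window` consecutive realised k values deviates from the
#' window mean by at most `stability_tol` everywhere.
#'
#' @inheritParams episignature
#' @param candidates Candidate sample IDs whose verified-positive count
#'   defines pseudo-sensitivity.
#' @param independent_controls Sample IDs for the specificity estimate
#'   (disjoint from training).
#' @param b_range,s_range Integer ranges for bootstraps and solution
#'   length; defaults 1:20 and 2:15 (280 configurations).
#' @param stability_tol Plateau tolerance (default 0.015, i.e. <= 1.5%
#'   deviation from the window mean).
#' @param window Number of consecutive realised k values per plateau
#'   window (default 5).
#' @return Object of class `"episig_sweep"`: `configurations` data.frame
#'   (b, s, k, specificity, n_positive, pseudo_sensitivity, failed),
#'   `by_k` per-length averages, `plateau` (named onset k per metric,
#'   `NA` when no window qualifies), ranges and tolerances.
#' @export
length_sweep <- function(m, case_ids, control_ids, candidates,
                         independent_controls, covariates = NULL,
                         b_range = 1:20, s_range = 2:15,
                         p_thresh = 5e-8, diff_thresh = 0.4, cost = 1,
                         stability_tol = 0.015, window = 5, seed = NULL) {
  stopifnot(length(b_range) >= 1, length(s_range) >= 1)
  grid <- expand.grid(b = b_range, s = s_range, KEEP.OUT.ATTRS = FALSE)
  seeds <- child_seeds(seed, nrow(grid))
  ic_m <- m[, independent_controls, drop = FALSE]

  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    fit <- tryCatch(
      episignature(m, case_ids, control_ids, covariates = covariates,
                   p_thresh = p_thresh, diff_thresh = diff_thresh,
                   b = grid$b[i], s = grid$s[i], cost = cost,
                   seed = seeds[[i]]),
      episig_empty_signature = function(e) NULL)
    if (is.null(fit)) {
      warning(sprintf("configuration b=%d s=%d yielded an empty signature; excluded",
                      grid$b[i], grid$s[i]))
      rows[[i]] <- data.frame(b = grid$b[i], s = grid$s[i], k = NA_integer_,
                              specificity = NA_real_, n_positive = NA_integer_,
                              failed = TRUE)
      next
    }
    spec <- evaluate_specificity(fit, ic_m)$specificity
    npos <- if (length(candidates))
      sum(predict(fit, m[, candidates, drop = FALSE]) >= 0.5) else 0L
    rows[[i]] <- data.frame(b = grid$b[i], s = grid$s[i],
                            k = length(fit$sites), specificity = spec,
                            n_positive = npos, failed = FALSE)
  }
  cfg <- do.call(rbind, rows)
  max_pos <- max(cfg$n_positive[!cfg$failed], 0, na.rm = TRUE)
  cfg$pseudo_sensitivity <- if (max_pos > 0) cfg$n_positive / max_pos else
    ifelse(cfg$failed, NA_real_, 0)

  ok <- cfg[!cfg$failed, , drop = FALSE]
  by_k <- do.call(rbind, lapply(split(ok, ok$k), function(d)
    data.frame(k = d$k[1], n_config = nrow(d),
               specificity = mean(d$specificity),
               pseudo_sensitivity = mean(d$pseudo_sensitivity))))
  by_k <- by_k[order(by_k$k), , drop = FALSE]
  rownames(by_k) <- NULL

  plateau <- c(
    specificity = plateau_onset(by_k$k, by_k$specificity, stability_tol, window),
    pseudo_sensitivity = plateau_onset(by_k$k, by_k$pseudo_sensitivity,
                                       stability_tol, window))

  structure(list(configurations = cfg, by_k = by_k, plateau = plateau,
                 b_range = b_range, s_range = s_range,
                 stability_tol = stability_tol, window = window),
            class = "episig_sweep")
}

# Smallest k from which the metric stays within tol of the mean of its
# window of `window` consecutive realised k values.
plateau_onset <- function(k, metric, tol, window) {
  n <- length(k)
  if (n < window) return(NA_integer_)
  for (i in seq_len(n - window + 1)) {
    w <- metric[i:(i + window - 1)]
    if (all(abs(w - mean(w)) <= tol)) return(k[i])
  }
  NA_integer_
}

#' @export
print.episig_sweep <- function(x, ...) {
  cat(sprintf("Episignature length sweep: %d configurations (b in %d..%d, s in %d..%d)\n",
              nrow(x$configurations), min(x$b_range), max(x$b_range),
              min(x$s_range), max(x$s_range)))
  cat(sprintf("  realised lengths k: %d distinct values in [%d, %d]\n",
              nrow(x$by_k), min(x$by_k$k), max(x$by_k$k)))
  cat(sprintf("  plateau onset: specificity k >= %s, pseudo-sensitivity k >= %s\n",
              x$plateau["specificity"], x$plateau["pseudo_sensitivity"]))
  invisible(x)
}

#' Plot a length sweep
#'
#' Average specificity (solid) and pseudo-sensitivity (dashed) against the
#' episignature length k.
#'
#' @param x An `"episig_sweep"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.episig_sweep <- function(x, ...) {
  with(x$by_k, {
    graphics::plot(k, specificity, type = "o", pch = 16, ylim = c(0, 1),
                   xlab = "episignature length k", ylab = "metric", ...)
    graphics::lines(k, pseudo_sensitivity, type = "o", lty = 2, pch = 1)
    graphics::legend("bottomright", c("specificity", "pseudo-sensitivity"),
                     lty = c(1, 2), pch = c(16, 1), bty = "n")
  })
  invisible(x)
}

#' Rank-sum comparison of sub-threshold scores
#'
#' One-sided Wilcoxon rank-sum test (with continuity correction) comparing
#' the scores of variant carriers below the independent-control 95th score
#' percentile with the scores of independent controls below that level.
#' Members of the same family are collapsed to their per-family mean first.
#'
#' @param vus_scores Named numeric vector of carrier scores.
#' @param control_scores Numeric vector of independent-control scores.
#' @param q95 The 95th percentile score level used as ceiling filter.
#' @param families Optional character vector of family IDs aligned with
#'   `vus_scores`; `NA` means a singleton family.
#' @return `htest` object from [stats::wilcox.test()] (alternative:
#'   carriers greater).
#' @export
compare_subthreshold_scores <- function(vus_scores, control_scores, q95,
                                        families = NULL) {
  if (!is.null(families)) {
    stopifnot(length(families) == length(vus_scores))
    fam <- ifelse(is.na(families), paste0(".solo", seq_along(vus_scores)),
                  as.character(families))
    vus_scores <- tapply(vus_scores, fam, mean)
  }
  v <- vus_scores[vus_scores < q95]
  ctl <- control_scores[control_scores < q95]
  if (length(v) == 0 || length(ctl) == 0)
    stop_episig("a group is empty after the q95 filter")
  wilcox.test(v, ctl, alternative = "greater", correct = TRUE, exact = FALSE)
}
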