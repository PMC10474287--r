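#' Mean normalized methylation deviation
#'
#' Severity statistic of a sample against the control distribution: for
#' each episignature CpG site the z-value is the sample M-value minus the
#' control mean at that site, divided by the control SD (n-1 denominator);
#' the statistic is the mean absolute z over the signature sites. For a
#' control-like sample with many sites this tends to E|N(0,1)| =
#' sqrt(2/pi) ~ 0.798.
#'
#' @param m Sites x samples M-value matrix of the samples to score.
#' @param control_m Sites x controls M-value matrix defining the reference
#'   distribution (typically the training controls).
#' @param sites Episignature site IDs (subset of both matrices). Sites
#'   with zero control SD are dropped with a warning.
#' @return data.frame: `sample_id`, `deviation` (mean |z|), with the
#'   per-site z matrix in attribute `"z"`.
#' @export
mean_norm_meth_deviation <- function(m, control_m, sites) {
  sites <- as.character(sites)
  miss <- setdiff(sites, intersect(rownames(m), rownames(control_m)))
  if (length(miss))
    stop_episig("site(s) absent from input: %s", paste(miss, collapse = ", "))
  mu <- rowMeans(control_m[sites, , drop = FALSE])
  sdv <- apply(control_m[sites, , drop = FALSE], 1, sd)
  drop <- sdv <= 0
  if (any(drop)) {
    warning(sprintf("%d site(s) with zero control SD dropped", sum(drop)))
    sites <- sites[!drop]; mu <- mu[!drop]; sdv <- sdv[!drop]
    if (!length(sites)) stop_episig("no usable signature site left")
  }
  z <- (m[sites, , drop = FALSE] - mu) / sdv
  out <- data.frame(sample_id = colnames(m), deviation = colMeans(abs(z)),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "z") <- z
  out
}

#' Association of the severity statistic with age at onset
#'
#' Single-covariate Cox proportional-hazards regression of age at onset on
#' the mean normalized methylation deviation, with right-censoring for
#' carriers in whom the phenotype had not occurred at examination, Breslow
#' tie handling, and a maximum-likelihood-ratio test against the null
#' model. A hazard ratio > 1 means higher deviation predicts earlier
#' onset.
#'
#' @param scores Numeric severity scores, one per sample.
#' @param age_at_onset Onset age, or age at examination for censored
#'   samples.
#' @param observed 0/1 (or logical) event indicator; at least 3 events
#'   required.
#' @return List with `hazard_ratio`, `ci` (95% Wald), `lr_stat`, `p`
#'   (likelihood-ratio), and the `survival::coxph` `fit`.
#' @export
onset_association <- function(scores, age_at_onset, observed) {
  observed <- as.integer(observed)
  stopifnot(length(scores) == length(age_at_onset),
            length(scores) == length(observed))
  if (!all(is.finite(scores))) stop_episig("scores must be finite")
  if (sum(observed) == 0) stop_episig("no observed events: cannot fit")
  if (sum(observed) < 3) stop_episig("need at least 3 observed events")
  fit <- survival::coxph(survival::Surv(age_at_onset, observed) ~ scores,
                         ties = "breslow")
  s <- summary(fit)
  list(hazard_ratio = unname(exp(coef(fit))),
       ci = unname(s$conf.int[1, c("lower .95", "upper .95")]),
       lr_stat = unname(s$logtest["test"]),
       p = unname(s$logtest["pvalue"]),
       fit = fit)
}

#' Pearson correlation with an age proxy for censored onsets
#'
#' Correlates the severity statistic with age at onset, substituting the
#' age at examination as a proxy for the (unobserved) onset age of
#' censored samples.
#'
#' @inheritParams onset_association
#' @param age Age at examination, used for censored samples.
#' @return List with `r`, `r_squared`, `p` (two-sided), `n`.
#' @export
correlation_with_proxy <- function(scores, age_at_onset, observed, age) {
  observed <- as.logical(observed)
  y <- ifelse(observed, age_at_onset, age)
  if (anyNA(y) || anyNA(scores)) stop_episig("combined vector must be complete")
  if (length(y) < 3) stop_episig("need at least 3 points")
  ct <- stats::cor.test(scores, y, method = "pearson")
  list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
       p = ct$p.value, n = length(y))
}
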