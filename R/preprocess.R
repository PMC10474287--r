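#' Convert methylation beta values to M-values
#'
#' The M-value is the logit (base 2) of the methylation fraction,
#' `M = log2(beta / (1 - beta))`. Statistics downstream (EWAS, feature
#' selection, classification, z-scores) all operate on the M scale, which is
#' approximately variance-stabilised compared with the bounded beta scale.
#'
#' @param beta Numeric vector or matrix of methylation fractions, strictly
#'   inside (0, 1). Matrices are sites x samples.
#' @return Object of the same shape with M-values.
#' @seealso [m_to_beta()] for the inverse transform.
#' @examples
#' beta_to_m(0.5)           # 0
#' beta_to_m(0.8)           # 2
#' m_to_beta(beta_to_m(0.3))
#' @export
beta_to_m <- function(beta) {
  bad <- which(!is.na(beta) & (beta <= 0 | beta >= 1))
  if (length(bad)) {
    lab <- if (is.matrix(beta)) {
      ij <- arrayInd(bad[1], dim(beta))
      sprintf("site %s, sample %s",
              rownames(beta)[ij[1]] %||% ij[1], colnames(beta)[ij[2]] %||% ij[2])
    } else sprintf("position %d", bad[1])
    stop_episig("beta values must lie strictly in (0,1); first offender at %s (value %g)",
                lab, beta[bad[1]])
  }
  log2(beta / (1 - beta))
}

#' @rdname beta_to_m
#' @param m Numeric vector or matrix of M-values.
#' @export
m_to_beta <- function(m) {
  p <- 2^m
  p / (1 + p)
}

#' Probe-level quality filtering
#'
#' Removes CpG probes that fail any of the array QC rules: detection p-value
#' above `det_p_thresh` (by default in any sample; set
#' `det_p_rule = "fraction"` to require failure in more than
#' `1 - call_rate_thresh` of samples), membership in a mask list (sex
#' chromosomes, SNP overlap, cross-reactivity), or per-probe call rate below
#' `call_rate_thresh` (fraction of non-missing values).
#'
#' @param beta Sites x samples beta matrix (may contain `NA`).
#' @param detection_p Optional matrix of detection p-values, same shape.
#' @param masks Named list of character vectors of probe IDs to drop, e.g.
#'   `list(sex_chromosome = ..., snp_overlap = ..., cross_reactive = ...)`.
#'   IDs absent from the matrix raise a warning, not an error.
#' @param det_p_thresh Detection p-value cutoff (default 0.01).
#' @param call_rate_thresh Minimum per-probe call rate (default 0.95).
#' @param det_p_rule `"any"` (strict, default) or `"fraction"`.
#' @return The filtered matrix with attribute `"exclusions"`, a data.frame
#'   of `(id, reason)`; the first failing rule in the order
#'   mask > detection_p > call_rate is reported.
#' @export
filter_probes <- function(beta, detection_p = NULL, masks = list(),
                          det_p_thresh = 0.01, call_rate_thresh = 0.95,
                          det_p_rule = c("any", "fraction")) {
  assert_matrix_like(beta, "beta")
  det_p_rule <- match.arg(det_p_rule)
  stopifnot(det_p_thresh > 0, det_p_thresh <= 1,
            call_rate_thresh > 0, call_rate_thresh <= 1)
  ids <- rownames(beta)
  reason <- setNames(rep(NA_character_, length(ids)), ids)

  for (mname in names(masks)) {
    mask <- masks[[mname]]
    unknown <- setdiff(mask, ids)
    if (length(unknown))
      warning(sprintf("mask '%s' references %d unknown probe ID(s)",
                      mname, length(unknown)))
    hit <- intersect(mask, ids)
    reason[hit][is.na(reason[hit])] <- mname
  }
  if (!is.null(detection_p)) {
    stopifnot(identical(dim(detection_p), dim(beta)))
    fail <- if (det_p_rule == "any") {
      apply(detection_p > det_p_thresh, 1, any, na.rm = TRUE)
    } else {
      rowMeans(detection_p > det_p_thresh, na.rm = TRUE) > (1 - call_rate_thresh)
    }
    reason[fail & is.na(reason)] <- "detection_p"
  }
  call_rate <- rowMeans(!is.na(beta))
  reason[call_rate < call_rate_thresh & is.na(reason)] <- "call_rate"

  keep <- is.na(reason)
  out <- beta[keep, , drop = FALSE]
  attr(out, "exclusions") <- data.frame(
    id = ids[!keep], reason = unname(reason[!keep]),
    stringsAsFactors = FALSE)
  out
}

#' Sample-level quality filtering
#'
#' Drops samples whose mean detection p-value exceeds `mean_det_p_thresh`
#' or whose call rate (fraction of non-missing probes) falls below
#' `call_rate_thresh`.
#'
#' @inheritParams filter_probes
#' @param mean_det_p_thresh Mean detection p-value cutoff (default 0.05).
#' @return Filtered matrix with attribute `"exclusions"` as in
#'   [filter_probes()]. Raises an error if no sample survives.
#' @export
filter_samples <- function(beta, detection_p = NULL,
                           mean_det_p_thresh = 0.05, call_rate_thresh = 0.95) {
  assert_matrix_like(beta, "beta")
  stopifnot(mean_det_p_thresh > 0, mean_det_p_thresh <= 1,
            call_rate_thresh > 0, call_rate_thresh <= 1)
  ids <- colnames(beta)
  reason <- setNames(rep(NA_character_, length(ids)), ids)
  if (!is.null(detection_p)) {
    stopifnot(identical(dim(detection_p), dim(beta)))
    mdp <- colMeans(detection_p, na.rm = TRUE)
    reason[mdp > mean_det_p_thresh] <- "mean_detection_p"
  }
  call_rate <- colMeans(!is.na(beta))
  reason[call_rate < call_rate_thresh & is.na(reason)] <- "call_rate"
  keep <- is.na(reason)
  if (!any(keep))
    stop_episig("all samples failed QC; empty cohort", class = "episig_empty_cohort")
  out <- beta[, keep, drop = FALSE]
  attr(out, "exclusions") <- data.frame(
    id = ids[!keep], reason = unname(reason[!keep]), stringsAsFactors = FALSE)
  out
}

#' PCA confidence-ellipse outlier detection
#'
#' Projects samples onto the first two principal components of the centred
#' M-value matrix and classifies each sample against the confidence ellipse
#' containing `coverage` of a bivariate normal: the set of points whose
#' squared Mahalanobis distance (under the empirical covariance of the PC
#' scores) is at most the chi-square(2) quantile at `coverage`. Samples
#' within `border_tol` (relative) of the boundary are labelled `"border"`.
#'
#' @param m Sites x samples M-value matrix, complete cases.
#' @param coverage Ellipse coverage probability (default 0.99).
#' @param border_tol Relative width of the border zone (default 0.01).
#' @return data.frame with `sample_id`, `pc1`, `pc2`, `dist2` (squared
#'   Mahalanobis distance) and `classification` in
#'   `c("inside", "border", "outside")`.
#' @export
pca_outlier_ellipse <- function(m, coverage = 0.99, border_tol = 0.01) {
  assert_matrix_like(m, "M-value matrix")
  if (ncol(m) < 3) stop_episig("need at least 3 samples for a PCA ellipse")
  if (anyNA(m)) stop_episig("PCA requires complete cases; filter first")
  pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  if (ncol(pc$x) < 2 || pc$sdev[2] < .Machine$double.eps^0.5)
    stop_episig("input is rank-deficient: fewer than 2 non-degenerate principal components")
  xy <- pc$x[, 1:2, drop = FALSE]
  S <- stats::cov(xy)
  d2 <- stats::mahalanobis(xy, center = colMeans(xy), cov = S)
  q <- qchisq(coverage, df = 2)
  cls <- ifelse(d2 > q * (1 + border_tol), "outside",
                ifelse(d2 >= q * (1 - border_tol), "border", "inside"))
  data.frame(sample_id = colnames(m), pc1 = xy[, 1], pc2 = xy[, 2],
             dist2 = d2, classification = cls,
             row.names = NULL, stringsAsFactors = FALSE)
}
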