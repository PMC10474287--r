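#' Epigenome-wide association analysis on M-values
#'
#' Per-CpG ordinary-least-squares regression of M-values on case/control
#' status with optional numeric covariates (sex, age, estimated blood-cell
#' fractions, ...). The reported test is the two-sided t-test on the status
#' coefficient. An optional moderated mode shrinks the residual variances
#' with an empirical-Bayes prior (via \pkg{limma}) before forming the
#' t-statistics.
#'
#' Constant sites (zero variance overall, hence no information) are flagged
#' and reported with effect 0 and p = 1 rather than dropped, so the result
#' always has one row per input site.
#'
#' @param m Sites x samples M-value matrix.
#' @param status Binary vector (0 = control, 1 = case), or logical, aligned
#'   with the columns of `m`. Both classes must be present.
#' @param covariates Optional numeric matrix/data.frame of per-sample
#'   covariates (no intercept column; one is added internally).
#' @param moderated If `TRUE`, squeeze residual variances with
#'   `limma::squeezeVar()` before computing t and p.
#' @return data.frame of class `"ewas_result"` with one row per site:
#'   `site_id`, `effect` (adjusted case-control M difference), `mean_diff`
#'   (raw case mean minus control mean), `t`, `p`, `constant` flag.
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(50 * 12), 50, 12,
#'             dimnames = list(sprintf("cg%02d", 1:50), sprintf("s%02d", 1:12)))
#' status <- rep(c(0, 1), each = 6)
#' m["cg01", status == 1] <- m["cg01", status == 1] + 4
#' res <- fit_ewas(m, status)
#' head(res[order(res$p), ])
#' @export
fit_ewas <- function(m, status, covariates = NULL, moderated = FALSE) {
  assert_matrix_like(m, "M-value matrix")
  status <- as.numeric(status)
  if (length(status) != ncol(m))
    stop_episig("status length (%d) does not match sample count (%d)",
                length(status), ncol(m))
  if (!all(status %in% c(0, 1)) || length(unique(status)) < 2)
    stop_episig("status must be binary 0/1 with both classes present")
  if (anyNA(m)) stop_episig("EWAS requires complete cases")

  X <- cbind(`(Intercept)` = 1, status = status)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == ncol(m))
    storage.mode(covariates) <- "double"
    colnames(covariates) <- colnames(covariates) %||%
      paste0("cov", seq_len(ncol(covariates)))
    X <- cbind(X, covariates)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop_episig("collinear design: covariate matrix with intercept and status is rank-deficient")
  n <- nrow(X); p <- ncol(X); df <- n - p

  # One shared design across all sites: solve for all responses at once.
  B <- qr.coef(qx, t(m))                      # p x sites
  res <- t(m) - X %*% B                       # n x sites residuals
  rss <- colSums(res^2)
  s2 <- rss / df
  xtx_inv_ss <- solve(crossprod(X))["status", "status"]

  const <- apply(m, 1, function(r) diff(range(r)) < .Machine$double.eps^0.5)
  eff <- B["status", ]

  if (moderated) {
    if (!requireNamespace("limma", quietly = TRUE))
      stop_episig("moderated mode requires the 'limma' package")
    sq <- limma::squeezeVar(s2[!const], df = df)
    s2m <- s2; s2m[!const] <- sq$var.post
    dfm <- df + (if (is.finite(sq$df.prior)) sq$df.prior else 1e6)
    tval <- eff / sqrt(s2m * xtx_inv_ss)
    pval <- 2 * pt(-abs(tval), df = dfm)
  } else {
    tval <- eff / sqrt(s2 * xtx_inv_ss)
    pval <- 2 * pt(-abs(tval), df = df)
  }
  eff[const] <- 0; tval[const] <- 0; pval[const] <- 1

  mean_diff <- rowMeans(m[, status == 1, drop = FALSE]) -
    rowMeans(m[, status == 0, drop = FALSE])

  out <- data.frame(site_id = rownames(m), effect = unname(eff),
                    mean_diff = unname(mean_diff), t = unname(tval),
                    p = unname(pval), constant = unname(const),
                    stringsAsFactors = FALSE)
  class(out) <- c("ewas_result", "data.frame")
  out
}

#' Dual-threshold primary site selection
#'
#' Keeps sites that reach the significance threshold **and** exceed the
#' absolute raw mean M-value difference threshold, ordered by ascending p.
#' Both conditions are strict inequalities.
#'
#' @param res An `"ewas_result"` from [fit_ewas()].
#' @param p_thresh Significance threshold (default genome-wide 5e-8; relax
#'   for small simulated site sets).
#' @param diff_thresh Minimum absolute mean M difference (default 0.4).
#' @return Character vector of selected site IDs ordered by ascending p,
#'   with attribute `"table"` holding the selected rows. Empty selections
#'   are returned as a zero-length vector with a warning; downstream stages
#'   treat this as an explicit empty-signature condition.
#' @export
select_sites <- function(res, p_thresh = 5e-8, diff_thresh = 0.4) {
  stopifnot(inherits(res, "ewas_result") ||
              all(c("site_id", "p", "mean_diff") %in% names(res)))
  stopifnot(p_thresh > 0, diff_thresh >= 0)
  keep <- res$p < p_thresh & abs(res$mean_diff) > diff_thresh
  sel <- res[keep, , drop = FALSE]
  sel <- sel[order(sel$p, sel$site_id), , drop = FALSE]
  if (nrow(sel) == 0) warning("empty signature: no site passed both thresholds")
  out <- sel$site_id
  attr(out, "table") <- sel
  out
}
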