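#' Gaussian mutual information from the Pearson correlation
#'
#' `MI(x, y) = -ln(1 - rho^2) / 2` nats, with `rho` the Pearson correlation
#' between the two vectors. For a binary phenotype encoded 0/1 this is the
#' point-biserial correlation. The estimate is symmetric in its arguments.
#'
#' Constant vectors have undefined correlation; their MI is defined as 0
#' with a warning. A perfect correlation (|rho| = 1) would be infinite and
#' is capped at a large finite value, also with a warning.
#'
#' @param x,y Numeric (or binary 0/1) vectors of equal length >= 3.
#' @return Mutual information in nats.
#' @examples
#' mutual_info(1:10, (1:10)^2)
#' -log(1 - 0.6^2) / 2  # MI at rho = 0.6
#' @export
mutual_info <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 3)
    stop_episig("x and y must have equal length >= 3")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant vector: MI defined as 0")
    return(0)
  }
  r2 <- cor(x, y)^2
  if (r2 >= 1 - 1e-12) {
    warning("|rho| = 1: MI capped at a finite value")
    r2 <- 1 - 1e-12
  }
  -log(1 - r2) / 2
}

# Vectorised MI of every column of `mat` with vector `v` (internal hot path).
mi_cols <- function(mat, v) {
  sds <- apply(mat, 2, sd)
  r <- rep(0, ncol(mat))
  ok <- sds > 0 & sd(v) > 0
  if (any(ok)) r[ok] <- as.vector(cor(mat[, ok, drop = FALSE], v))
  r2 <- pmin(r^2, 1 - 1e-12)
  -log(1 - r2) / 2
}

#' Classical greedy mRMR feature selection
#'
#' Minimum-redundancy-maximum-relevance selection over candidate CpG sites.
#' The first site maximises MI with the phenotype; each subsequent site
#' maximises `MI(x_i, y) - mean_j MI(x_i, x_j)` over the already-selected
#' set S (redundancy penalised by its mean MI with S). Selection stops at
#' `max_size` sites or when candidates are exhausted.
#'
#' Score ties are broken by ascending `priority` (typically the EWAS
#' p-value), then by site ID, so the selection is deterministic.
#'
#' @param x Samples x sites numeric matrix of M-values at candidate sites
#'   (column names are site IDs).
#' @param y Binary phenotype vector (0/1), one per row of `x`.
#' @param max_size Maximum number of sites to select (`>= 1`).
#' @param priority Optional numeric vector per site used for tie-breaking
#'   (lower wins); defaults to column order-independent site-ID ordering.
#' @return Character vector of selected site IDs in selection order, with
#'   attribute `"scores"` (the greedy score at each pick).
#' @export
mrmr_classic <- function(x, y, max_size, priority = NULL) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (!is.numeric(max_size) || max_size < 1) stop_episig("max_size must be >= 1")
  if (ncol(x) < 1) stop_episig("need at least one candidate site")
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(x))
  priority <- priority %||% rep(0, ncol(x))
  stopifnot(length(priority) == ncol(x))

  ids <- colnames(x)
  relevance <- mi_cols(x, y)
  names(relevance) <- ids
  # redundancy cache: MI between each candidate and each selected site
  selected <- character(0)
  sel_scores <- numeric(0)
  red_sum <- setNames(rep(0, ncol(x)), ids)
  remaining <- ids

  pick_best <- function(score, pool) {
    o <- order(-score, priority[match(pool, ids)], pool)
    pool[o[1]]
  }

  while (length(selected) < max_size && length(remaining) > 0) {
    if (length(selected) == 0) {
      score <- relevance[remaining]
    } else {
      score <- relevance[remaining] - red_sum[remaining] / length(selected)
    }
    best <- pick_best(unname(score), remaining)
    selected <- c(selected, best)
    sel_scores <- c(sel_scores, unname(score[best]))
    remaining <- setdiff(remaining, best)
    if (length(remaining) > 0)
      red_sum[remaining] <- red_sum[remaining] +
        mi_cols(x[, remaining, drop = FALSE], x[, best])
  }
  attr(selected, "scores") <- sel_scores
  selected
}

#' Bootstrap-ensemble mRMR selection
#'
#' Runs classical greedy mRMR on `b` class-stratified bootstrap resamples of
#' the samples (cases and controls resampled separately, preserving the
#' class counts so no bootstrap loses a class) and returns the union of the
#' per-bootstrap selections. The union is at most `b * s` sites; on
#' correlated site sets it is typically much smaller, which is the point of
#' the ensemble: redundant sites split votes while independently informative
#' sites recur across bootstraps.
#'
#' @inheritParams mrmr_classic
#' @param b Number of bootstraps (>= 1).
#' @param s Per-bootstrap solution length `max(|S|)`.
#' @param seed Integer seed; the resamples (and hence the result) are
#'   deterministic given the seed.
#' @param identity_resample If `TRUE` (and `b == 1`), skip resampling so the
#'   single run equals [mrmr_classic()].
#' @return Object of class `"mrmr_selection"`: a list with `union`
#'   (site IDs, ordered by number of supporting bootstraps then first pick
#'   rank), `per_bootstrap` (list of ordered selections), `support` (named
#'   count of bootstraps choosing each site), `b`, `s`, `seed`.
#' @export
mrmr_ensemble_bootstrap <- function(x, y, b = 20, s = 15, seed = NULL,
                                    priority = NULL, identity_resample = FALSE) {
  if (!is.matrix(x)) x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(b >= 1, s >= 1, length(y) == nrow(x))
  cls <- unique(y)
  if (length(cls) != 2 || min(table(y)) < 2)
    stop_episig("need at least 2 samples in each of the two classes")

  runs <- with_seed(seed, {
    lapply(seq_len(b), function(i) {
      idx <- if (identity_resample) seq_along(y) else {
        unlist(lapply(cls, function(k) {
          rows <- which(y == k)
          sample(rows, length(rows), replace = TRUE)
        }))
      }
      mrmr_classic(x[idx, , drop = FALSE], y[idx], max_size = s,
                   priority = priority)
    })
  })
  support <- table(unlist(lapply(runs, unique)))
  first_rank <- sapply(names(support), function(id)
    min(unlist(lapply(runs, function(r) {
      w <- match(id, r); if (is.na(w)) Inf else w
    }))))
  ord <- order(-as.integer(support), first_rank, names(support))
  structure(list(
    union = names(support)[ord],
    per_bootstrap = runs,
    support = setNames(as.integer(support), names(support))[ord],
    first_rank = first_rank[ord],
    b = b, s = s, seed = seed), class = "mrmr_selection")
}

#' @export
print.mrmr_selection <- function(x, ...) {
  cat(sprintf("Bootstrap-ensemble mRMR selection: %d sites (b = %d, s = %d, bound %d)\n",
              length(x$union), x$b, x$s, x$b * x$s))
  cat("Top sites by bootstrap support:\n")
  print(head(x$support, 10))
  invisible(x)
}
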