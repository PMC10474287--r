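# Internal helpers shared across modules.

# Run `expr` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library code never perturbs the
# user's stream. seed = NULL runs in the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Fan one parent seed out into k reproducible child seeds (< 2^31).
child_seeds <- function(seed, k) {
  if (is.null(seed)) return(rep(list(NULL), k))
  with_seed(seed, as.list(sample.int(.Machine$integer.max - 1L, k)))
}

stop_episig <- function(fmt, ..., class = "episig_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "episig_error")))
}

assert_matrix_like <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    stop_episig("%s must be a numeric matrix with sites in rows and samples in columns", what)
  if (is.null(rownames(x)) || anyDuplicated(rownames(x)))
    stop_episig("%s must have unique rownames (CpG site IDs)", what)
  if (is.null(colnames(x)) || anyDuplicated(colnames(x)))
    stop_episig("%s must have unique colnames (sample IDs)", what)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
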