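test_that("Gaussian MI matches the closed form and is symmetric", {
  set.seed(41)
  x <- rnorm(50); y <- 0.6 * x + rnorm(50)
  expect_equal(mutual_info(x, y), -log(1 - cor(x, y)^2) / 2)
  expect_equal(mutual_info(x, y), mutual_info(y, x))
  # exactly rho = 0.6: MI = -ln(0.64)/2
  expect_equal(-log(1 - 0.36) / 2, 0.22314355, tolerance = 1e-7)
  # uncorrelated constants and caps
  expect_warning(mi0 <- mutual_info(rep(1, 10), rnorm(10)), "constant")
  expect_equal(mi0, 0)
  expect_warning(mi_cap <- mutual_info(1:10, 2 * (1:10) + 3), "capped")
  expect_true(is.finite(mi_cap) && mi_cap > 10)
})

test_that("greedy choice equals brute-force score maximization (<= 8 features)", {
  set.seed(42)
  n <- 40
  for (rep in 1:5) {
    base <- matrix(rnorm(n * 4), n, 4)
    x <- cbind(base,
               base[, 1] + rnorm(n, 0, 0.3),     # redundant with f1
               base[, 2] + rnorm(n, 0, 0.5),
               rnorm(n), rnorm(n))
    colnames(x) <- sprintf("f%d", 1:8)
    y <- as.numeric(base[, 1] + base[, 2] - base[, 3] + rnorm(n) > 0)
    got <- mrmr_classic(x, y, max_size = 8)
    expect_identical(as.character(got), mrmr_oracle(x, y, 8))
  }
})

test_that("a duplicated feature is never selected right after its copy", {
  set.seed(43)
  n <- 60
  f1 <- rnorm(n)
  x <- cbind(f1 = f1, f2 = f1, f3 = rnorm(n))
  y <- as.numeric(f1 + 0.8 * x[, "f3"] + rnorm(n, 0, 0.6) > 0)
  sel <- mrmr_classic(x, y, max_size = 3)
  expect_true(sel[1] %in% c("f1", "f2"))
  expect_identical(sel[2], "f3")     # the exact copy is maximally redundant
  # single candidate trivially selected
  expect_identical(as.character(mrmr_classic(x[, 1, drop = FALSE], y, 5)), "f1")
  expect_error(mrmr_classic(x, y, max_size = 0), "max_size")
})

test_that("selection order is invariant to input column order", {
  set.seed(44)
  x <- matrix(rnorm(50 * 6), 50, 6, dimnames = list(NULL, sprintf("f%d", 1:6)))
  y <- as.numeric(x[, 1] + x[, 4] + rnorm(50) > 0)
  s1 <- mrmr_classic(x, y, 6)
  s2 <- mrmr_classic(x[, sample(6)], y, 6)
  expect_identical(as.character(s1), as.character(s2))
})

test_that("greedy prefixes are monotone in the solution length", {
  set.seed(45)
  x <- matrix(rnorm(40 * 7), 40, 7, dimnames = list(NULL, sprintf("f%d", 1:7)))
  y <- as.numeric(x[, 2] - x[, 5] + rnorm(40) > 0)
  full <- mrmr_classic(x, y, 7)
  for (s in 1:6)
    expect_identical(as.character(mrmr_classic(x, y, s)), full[1:s])
})

test_that("bootstrap ensemble: identity resample equals classic, bound holds, deterministic", {
  set.seed(46)
  x <- matrix(rnorm(30 * 10), 30, 10, dimnames = list(NULL, sprintf("f%02d", 1:10)))
  y <- rep(c(0, 1), each = 15)
  one <- mrmr_ensemble_bootstrap(x, y, b = 1, s = 4, identity_resample = TRUE)
  expect_setequal(one$union, as.character(mrmr_classic(x, y, 4)))
  ens1 <- mrmr_ensemble_bootstrap(x, y, b = 6, s = 3, seed = 9)
  ens2 <- mrmr_ensemble_bootstrap(x, y, b = 6, s = 3, seed = 9)
  expect_identical(ens1$union, ens2$union)
  expect_lte(length(ens1$union), 6 * 3)
  expect_true(all(ens1$support >= 1))
  expect_error(mrmr_ensemble_bootstrap(x, rep(0, 30), b = 2, s = 2), "classes")
})

test_that("ensemble compresses redundant sites and keeps independent informative ones", {
  seeds_hit <- vapply(1:10, function(sd) {
    set.seed(sd * 100)
    n <- 40
    # 5 latent signals, each echoed by 10 noisy redundant sites; 10 further
    # sites are mutually independent and individually informative
    latent <- matrix(rnorm(n * 5), n, 5)
    informative <- matrix(rnorm(n * 10), n, 10)
    y <- as.numeric(rowMeans(informative) + 0.5 * rowMeans(latent) +
                      rnorm(n, 0, 0.4) > 0)
    redundant <- latent[, rep(1:5, each = 10)] +
      matrix(rnorm(n * 50, 0, 0.2), n, 50)
    x <- cbind(redundant, informative)
    colnames(x) <- c(sprintf("red%02d", 1:50), sprintf("ind%02d", 1:10))
    ens <- mrmr_ensemble_bootstrap(x, y, b = 20, s = 15, seed = sd)
    c(smaller = length(ens$union) < 60,
      kept = sum(sprintf("ind%02d", 1:10) %in% ens$union) >= 8)
  }, logical(2))
  expect_true(all(seeds_hit["smaller", ]))
  expect_gte(mean(seeds_hit["kept", ]), 0.9)
})
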