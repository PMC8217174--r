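# Conditional-independence tests: exact oracles, calibration, power, and the
# permutation engine contract.

test_that("parcorr equals the covariance-inverse partial correlation exactly", {
  set.seed(10)
  n <- 50
  D <- matrix(rnorm(n * 5), n, 5)
  D[, 2] <- 0.6 * D[, 1] + 0.4 * D[, 2]
  D[, 3] <- 0.5 * D[, 2] + 0.5 * D[, 3]
  for (conds in list(3L, c(3L, 4L), c(3L, 4L, 5L))) {
    S <- cov(D)
    expected <- partial_cor_oracle(S, 1, 2, conds)
    res <- parcorr(D[, 1], D[, 2], D[, conds, drop = FALSE], n_perm = 9,
                   seed = 1, block_len = 2)
    expect_equal(res$statistic, expected, tolerance = 1e-10)
  }
  # identical series: statistic exactly 1
  x <- rnorm(100)
  expect_equal(parcorr(x, x, n_perm = 9, seed = 1)$statistic, 1)
})

test_that("parcorr removes the middle node of a Gaussian chain", {
  hits <- 0
  for (s in 1:20) {
    set.seed(100 + s)
    n <- 2000
    x <- rnorm(n)
    y <- 0.8 * x + 0.6 * rnorm(n)
    z <- 0.8 * y + 0.6 * rnorm(n)
    res <- parcorr(x, z, matrix(y), n_perm = 199, seed = s)
    if (res$p_value > 0.01) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("rank-deficient conditioning sets are repaired with a warning", {
  set.seed(11)
  x <- rnorm(200)
  y <- rnorm(200)
  Z <- cbind(z1 = rnorm(200), z2 = 0)
  expect_warning(res <- parcorr(x, y, Z, n_perm = 19, seed = 1),
                 "rank-deficient")
  expect_true(is.finite(res$statistic))
  expect_error(parcorr(rnorm(5), rnorm(5), n_perm = 9), "too small")
})

test_that("gpdc detects quadratic dependence that parcorr misses", {
  both <- 0
  for (s in 1:10) {
    set.seed(200 + s)
    n <- 1000
    x <- rnorm(n)
    y <- x^2 + 0.5 * rnorm(n)
    p_lin <- parcorr(x, y, n_perm = 199, seed = s)$p_value
    p_gp <- gpdc(x, y, n_perm = 199, seed = s)$p_value
    if (p_gp < 0.01 && p_lin > 0.01) both <- both + 1
  }
  expect_gte(both, 8)
})

test_that("gpdc also detects plain linear dependence", {
  set.seed(12)
  n <- 1000
  x <- rnorm(n)
  y <- 0.8 * x + rnorm(n)
  expect_lt(gpdc(x, y, n_perm = 199, seed = 3)$p_value, 0.01)
})

test_that("gpdc residualizes on Z with Gaussian-process regression", {
  set.seed(13)
  n <- 400
  z <- rnorm(n)
  x <- sin(2 * z) + 0.3 * rnorm(n)
  y <- sin(2 * z) + 0.3 * rnorm(n)
  # x and y are dependent only through z; GP regression must absorb it
  res <- gpdc(x, y, matrix(z), n_perm = 199, seed = 5)
  expect_gt(res$p_value, 0.01)
  res0 <- gpdc(x, y, n_perm = 199, seed = 5)
  expect_lt(res0$p_value, 0.01)
})

test_that("cmiknn approaches the Gaussian closed form", {
  set.seed(14)
  n <- 4000
  rho <- 0.6
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  res <- cmiknn(x, y, n_perm = 9, seed = 1)
  expect_lt(abs(res$statistic - (-0.5 * log(1 - rho^2))), 0.03)
})

test_that("cmiknn detects multiplicative noise better than the other tests", {
  wins <- 0
  for (s in 1:5) {
    set.seed(300 + s)
    n <- 2000
    x <- rnorm(n)
    y <- x * rnorm(n)
    p_cmi <- cmiknn(x, y, n_perm = 199, seed = s)$p_value
    if (p_cmi < 0.01) wins <- wins + 1
  }
  expect_gte(wins, 4)
})

test_that("statistics are symmetric in the tested pair", {
  set.seed(15)
  n <- 300
  x <- rnorm(n)
  y <- 0.5 * x + rnorm(n)
  Z <- matrix(rnorm(n))
  expect_equal(parcorr(x, y, Z, n_perm = 9, seed = 1)$statistic,
               parcorr(y, x, Z, n_perm = 9, seed = 1)$statistic,
               tolerance = 1e-12)
  expect_equal(gpdc(x, y, n_perm = 9, seed = 1)$statistic,
               gpdc(y, x, n_perm = 9, seed = 1)$statistic,
               tolerance = 1e-10)
  expect_equal(cmiknn(x, y, n_perm = 9, seed = 1)$statistic,
               cmiknn(y, x, n_perm = 9, seed = 1)$statistic,
               tolerance = 1e-10)
})

test_that("the permutation p-value formula and monotonicity contract hold", {
  # observed statistic beats every permutation: p = 1/(n_perm + 1)
  set.seed(16)
  n <- 400
  x <- seq_len(n) + rnorm(n, sd = 1e-3)
  y <- seq_len(n)
  p <- block_shuffle_pvalue(function(x, y, Z) cor(x, y), x, y,
                            n_perm = 99, block_len = 5, seed = 2)
  expect_equal(as.numeric(p), 1 / 100)
  # holding permutations fixed, a larger |observed| never increases p
  perm_stats <- attr(p, "perm_stats")
  obs_grid <- seq(0, 1, by = 0.05)
  ps <- vapply(obs_grid, function(o) bgmci:::p_from_perm(o, perm_stats),
               numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_error(
    block_shuffle_pvalue(function(x, y, Z) cor(x, y), x, y,
                         n_perm = 9, block_len = 200, seed = 1),
    "degenerate")
})

test_that("all three tests are calibrated at the 1% level under AR(1) nulls", {
  alpha <- 0.01
  n_seeds <- 200
  rej <- c(PC = 0, GPDC = 0, CMIknn = 0)
  for (s in seq_len(n_seeds)) {
    set.seed(400 + s)
    x <- as.numeric(arima.sim(list(ar = 0.3), 400))
    y <- as.numeric(arima.sim(list(ar = 0.3), 400))
    if (parcorr(x, y, n_perm = 99, seed = s)$p_value <= alpha)
      rej["PC"] <- rej["PC"] + 1
    if (s <= 100) {
      if (gpdc(x, y, n_perm = 99, seed = s)$p_value <= alpha)
        rej["GPDC"] <- rej["GPDC"] + 1
      if (cmiknn(x, y, n_perm = 99, seed = s)$p_value <= alpha)
        rej["CMIknn"] <- rej["CMIknn"] + 1
    }
  }
  # 99% binomial bounds around alpha
  expect_lte(rej[["PC"]], qbinom(0.995, n_seeds, alpha))
  expect_lte(rej[["GPDC"]], qbinom(0.995, 100, alpha))
  expect_lte(rej[["CMIknn"]], qbinom(0.995, 100, alpha))
})

test_that("block length matters for autocorrelated nulls", {
  n_seeds <- 100
  rej_auto <- 0
  rej_iid <- 0
  for (s in seq_len(n_seeds)) {
    set.seed(600 + s)
    x <- as.numeric(arima.sim(list(ar = 0.9), 500))
    y <- as.numeric(arima.sim(list(ar = 0.9), 500))
    if (parcorr(x, y, n_perm = 99, seed = s)$p_value <= 0.05)
      rej_auto <- rej_auto + 1
    if (parcorr(x, y, n_perm = 99, block_len = 1, seed = s)$p_value <= 0.05)
      rej_iid <- rej_iid + 1
  }
  # the autocorrelation rule keeps the size near nominal; sample-wise
  # shuffling inflates it badly
  expect_lte(rej_auto, qbinom(0.9995, n_seeds, 0.05) + 3)
  expect_gt(rej_iid, rej_auto)
  expect_gt(rej_iid / n_seeds, 0.15)
})

test_that("the default block length follows the autocorrelation decay", {
  set.seed(17)
  wn <- matrix(rnorm(1000), ncol = 1)
  expect_lte(default_block_len(wn), 3L)
  ar <- matrix(as.numeric(arima.sim(list(ar = 0.9), 1000)), ncol = 1)
  expect_gt(default_block_len(ar), 5L)
  expect_lte(default_block_len(ar), 50L)
})

test_that("the uniform interface dispatches and caches", {
  set.seed(18)
  x <- rnorm(300)
  y <- 0.5 * x + rnorm(300)
  cache <- tempfile("cicache")
  o <- list(n_perm = 49, seed = 3, cache_dir = cache)
  r1 <- ci_test(x, y, method = "PC", options = o)
  r2 <- ci_test(x, y, method = "PC", options = o)
  expect_identical(r1, r2)
  expect_length(list.files(cache), 1L)
  expect_s3_class(ci_test(x, y, method = "GPDC",
                          options = list(n_perm = 19, seed = 1)),
                  "ci_test_result")
  expect_s3_class(ci_test(x, y, method = "CMIknn",
                          options = list(n_perm = 19, seed = 1, k = 5)),
                  "ci_test_result")
  unlink(cache, recursive = TRUE)
})
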