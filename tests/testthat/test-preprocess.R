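# Signal-conditioning chain: nuisance regression, high-pass filter, pooled
# demeaning, concatenation with edge smoothing.

test_that("nuisance regression projects out the regressor", {
  set.seed(1)
  n <- 500
  nu <- rnorm(n)
  e <- rnorm(n)
  # a column equal to the nuisance becomes identically zero
  m <- cbind(a = nu, b = 2 * nu + e)
  r <- nuisance_regress(m, nu)
  expect_lt(max(abs(r[, "a"])), 1e-10)
  # the residual recovers the independent part up to OLS projection error
  expect_gt(cor(r[, "b"], e), 0.99)
  # residuals are orthogonal to the nuisance
  expect_lt(abs(sum(r[, "b"] * nu)), 1e-8 * n)
  # an orthogonal mean-zero column passes through unchanged
  nu2 <- rep(c(-1, 1), n / 2)
  x <- rep(c(1, 1, -1, -1), n / 4)  # orthogonal to nu2 and mean zero
  r2 <- nuisance_regress(matrix(x, ncol = 1), nu2)
  expect_equal(drop(r2), x, tolerance = 1e-12)
  expect_error(nuisance_regress(m, rep(1, n)), "zero variance")
  expect_error(nuisance_regress(m, rnorm(10)), "length")
})

test_that("high-pass filter removes slow drifts and keeps the passband", {
  tr <- 1.6
  n <- 2000
  t <- (0:(n - 1)) * tr
  # DC: a constant block maps to (numerically) zero
  const <- matrix(5, n, 1)
  expect_lt(max(abs(highpass_filter(const, repetition_time = tr))), 1e-8)
  # passband sinusoid at 0.05 Hz preserved within 1 dB
  s_pass <- sin(2 * pi * 0.05 * t)
  f_pass <- highpass_filter(s_pass, repetition_time = tr)
  ratio_pass <- fft_amplitude(f_pass, 0.05, tr) / fft_amplitude(s_pass, 0.05, tr)
  expect_gt(20 * log10(ratio_pass), -1)
  # stopband sinusoid at 0.004 Hz attenuated by at least 20 dB
  s_stop <- sin(2 * pi * 0.004 * t)
  f_stop <- highpass_filter(s_stop, repetition_time = tr)
  ratio_stop <- fft_amplitude(f_stop, 0.004, tr) / fft_amplitude(s_stop, 0.004, tr)
  expect_lt(20 * log10(ratio_stop), -20)
  expect_equal(length(f_pass), n)
  expect_error(highpass_filter(s_pass, cutoff_hz = 0.5, repetition_time = tr),
               "Nyquist")
})

test_that("filtering respects block boundaries", {
  set.seed(2)
  b1 <- matrix(rnorm(300), ncol = 1)
  b2 <- matrix(rnorm(300), ncol = 1)
  colnames(b1) <- colnames(b2) <- "R1"
  joined <- multichannel_series(rbind(b1, b2), repetition_time = 1.6,
                                boundaries = c(0L, 300L))
  f_joined <- highpass_filter(joined)
  f_sep <- rbind(highpass_filter(b1, repetition_time = 1.6),
                 highpass_filter(b2, repetition_time = 1.6))
  expect_equal(f_joined$values, f_sep, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("subject normalization demeans pooled, not per block", {
  blocks <- list(matrix(1, 4, 1), matrix(-1, 4, 1))
  out <- normalize_subject(blocks)
  pooled <- do.call(rbind, out)
  expect_equal(mean(pooled), 0)
  # pooled mean was already 0, so each block keeps its own mean of +/-1
  expect_equal(mean(out[[1]]), 1)
  expect_equal(mean(out[[2]]), -1)
  # a constant block becomes all zeros
  expect_equal(normalize_subject(list(matrix(7, 5, 2)))[[1]],
               matrix(0, 5, 2))
  # idempotence
  set.seed(3)
  blocks <- list(matrix(rnorm(40, mean = 3), 20, 2),
                 matrix(rnorm(40, mean = -1), 20, 2))
  once <- normalize_subject(blocks)
  twice <- normalize_subject(once)
  expect_equal(once, twice, tolerance = 1e-12)
})

test_that("concatenation records boundaries and only touches block edges", {
  set.seed(4)
  blocks <- lapply(1:3, function(i) {
    m <- matrix(rnorm(200), 100, 2)
    colnames(m) <- c("A", "B")
    m
  })
  out <- concatenate_blocks(blocks)
  expect_equal(nrow(out$values), 300)
  expect_equal(out$boundaries, c(0L, 100L, 200L))
  # boundaries partition the series
  expect_true(all(diff(c(out$boundaries, 300)) > 0))
  # interior samples are bit-identical; only the first and last 5 change
  expect_identical(out$values[6:95, ], blocks[[1]][6:95, ])
  expect_false(isTRUE(all.equal(out$values[1:5, ], blocks[[1]][1:5, ])))
  # a constant block stays constant under the moving average
  cblocks <- list(matrix(3, 50, 1))
  expect_equal(concatenate_blocks(cblocks)$values,
               matrix(3, 50, 1, dimnames = list(NULL, "R1")),
               ignore_attr = TRUE)
  bad <- blocks
  colnames(bad[[2]]) <- c("A", "C")
  expect_error(concatenate_blocks(bad), "region set")
})

test_that("the chain commutes with region relabeling and preserves the null", {
  d <- study_design(n_subjects = 2, blocks_per_condition = 2,
                    block_length = 100)
  gt <- list(motor = ground_truth(list(), "motor"),
             resting = ground_truth(list(), "resting"))
  s <- generate_study(d, gt, seed = 6, autocorr = 0)
  out <- preprocess_study(s)
  # null preservation: pairwise correlations of independent channels stay small
  cc <- cor(out$resting$values)
  n <- nrow(out$resting$values)
  expect_lt(max(abs(cc[upper.tri(cc)])), 3 / sqrt(n))
  # permuting columns before equals permuting after
  perm <- c(3, 1, 2, 5, 4, 8, 7, 6)
  s_perm <- s
  s_perm$blocks <- lapply(s$blocks, function(b) {
    b$values <- b$values[, perm]
    b
  })
  s_perm$regions <- s$regions[perm]
  out_perm <- preprocess_study(s_perm)
  expect_equal(out_perm$resting$values,
               out$resting$values[, perm], tolerance = 1e-12)
})
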