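# Two-stage discovery: parent selection, MCI conditioning, and graph-level
# invariants.

test_that("an AR(1) channel selects its own past as parent", {
  set.seed(20)
  vals <- matrix(as.numeric(arima.sim(list(ar = 0.8), 2000)), ncol = 1)
  colnames(vals) <- "X"
  cfg <- pcmci_config(n_perm = 99, seed = 1)
  ps <- select_parents(vals, cfg)
  expect_true(any(ps$X$region == "X" & ps$X$lag == 1))
  expect_equal(ps$X$region[1], "X")
  expect_equal(ps$X$lag[1], 1)
})

test_that("a planted lagged link is selected among the target's parents", {
  found <- 0
  for (s in 1:3) {
    b <- generate_block(bg_regions(),
                        list(coupling("M1", "Put", 1, "linear", 0.6)),
                        block_length = 2000, autocorr = 0.3, seed = 40 + s)
    cfg <- pcmci_config(n_perm = 99, seed = s)
    ps <- select_parents(b, cfg)
    if (any(ps$Put$region == "M1" & ps$Put$lag == 1)) found <- found + 1
  }
  expect_gte(found, 2)
})

test_that("MCI removes transitive chains and common-driver artifacts", {
  chain_ok <- 0
  driver_ok <- 0
  direct_ok <- 0
  for (s in 1:5) {
    # chain X -> Y -> Z at lag 1 each; X -> Z at lag 2 is indirect
    b <- generate_block(c("X", "Y", "Z"),
                        list(coupling("X", "Y", 1, "linear", 0.6),
                             coupling("Y", "Z", 1, "linear", 0.6)),
                        block_length = 4000, autocorr = 0.2, seed = 50 + s)
    cfg <- pcmci_config(n_perm = 199, seed = s)
    ps <- select_parents(b, cfg)
    if (mci_link_test(b, "X", "Z", 2, ps, cfg)$p_value > cfg$alpha)
      chain_ok <- chain_ok + 1
    if (mci_link_test(b, "X", "Y", 1, ps, cfg)$p_value < 0.01)
      direct_ok <- direct_ok + 1
    # common driver W -> U, W -> V: the contemporaneous U-V link is spurious
    b2 <- generate_block(c("W", "U", "V"),
                         list(coupling("W", "U", 1, "linear", 0.6),
                              coupling("W", "V", 1, "linear", 0.6)),
                         block_length = 4000, autocorr = 0.2, seed = 70 + s)
    ps2 <- select_parents(b2, cfg)
    if (mci_link_test(b2, "U", "V", 0, ps2, cfg)$p_value > cfg$alpha)
      driver_ok <- driver_ok + 1
  }
  expect_gte(chain_ok, 4)
  expect_gte(driver_ok, 4)
  expect_gte(direct_ok, 5)
  b <- generate_block(c("X", "Y"), list(), 200, seed = 1)
  ps <- select_parents(b, pcmci_config(n_perm = 19, seed = 1))
  expect_error(mci_link_test(b, "X", "Y", 5, ps, pcmci_config()),
               "exceeds tau_max")
})

test_that("the full run enumerates lags 0..tau_max over distinct pairs", {
  b <- generate_block(c("A", "B", "C"), list(), 400, seed = 3)
  cfg <- pcmci_config(n_perm = 19, seed = 2)
  g <- run_pcmci(b, cfg)
  expect_setequal(unique(g$all_tests$lag), 0:2)
  # 3 regions: 2 lags x 6 ordered pairs + 3 contemporaneous pairs
  expect_equal(nrow(g$all_tests), 2 * 6 + 3)
  expect_true(all(g$all_tests$source != g$all_tests$target))
  expect_true(all(g$links$p_value <= cfg$alpha))
})

test_that("the recovered graph is equivariant under region relabeling", {
  b <- generate_block(c("A", "B", "C", "D"),
                      list(coupling("A", "B", 1, "linear", 0.6),
                           coupling("C", "D", 0, "linear", 0.6)),
                      block_length = 800, autocorr = 0.2, seed = 7)
  cfg <- pcmci_config(n_perm = 99, seed = 4)
  g1 <- run_pcmci(b, cfg)
  perm <- c(4, 2, 1, 3)
  b2 <- b[, perm]
  g2 <- run_pcmci(b2, cfg)
  key <- function(g) {
    l <- g$links
    # lag-0 links are undirected; compare them orientation-free
    flip <- l$lag == 0 & l$source > l$target
    tmp <- l$source[flip]
    l$source[flip] <- l$target[flip]
    l$target[flip] <- tmp
    paste(l$source, l$target, l$lag, signif(l$statistic, 10), sep = "|")
  }
  expect_setequal(key(g1), key(g2))
})

test_that("pcmci matches a brute-force full-conditioning oracle on a small system", {
  b <- generate_block(c("X", "Y", "Z"),
                      list(coupling("X", "Y", 1, "linear", 0.7)),
                      block_length = 3000, autocorr = 0.2, seed = 9)
  cfg <- pcmci_config(tau_max = 1, n_perm = 199, seed = 5)
  g <- run_pcmci(b, cfg)
  # oracle: every link tested against the full conditioning set of all other
  # lagged variables (no parent selection)
  regions <- colnames(b)
  offset <- 2L
  n <- nrow(b)
  col_of <- function(i, lag) b[(offset + 1 - lag):(n - lag), i]
  brute <- list()
  for (i in 1:3) for (j in 1:3) {
    if (i == j) next
    Zfull <- sapply(setdiff(1:3, i), function(r) col_of(r, 1))
    res <- parcorr(col_of(i, 1), col_of(j, 0), Zfull, n_perm = 199, seed = 5)
    if (res$p_value <= 0.01) {
      brute[[length(brute) + 1L]] <- sprintf("%s>%s@1", regions[i], regions[j])
    }
  }
  got <- sprintf("%s>%s@%d", g$links$source, g$links$target, g$links$lag)
  expect_setequal(got[g$links$lag == 1], unlist(brute))
})

test_that("parent selection reports its sensitivity to the screening level", {
  b <- generate_block(c("X", "Y"), list(coupling("X", "Y", 1, "linear", 0.7)),
                      400, autocorr = 0.2, seed = 8)
  sens <- pc_alpha_sensitivity(b, pcmci_config(n_perm = 49, seed = 1),
                               pc_alphas = c(0.05, 0.3))
  expect_equal(nrow(sens), 4L)  # 2 levels x 2 regions
  # a looser screen never selects fewer parents
  n_tight <- sens$n_parents[sens$pc_alpha == 0.05]
  n_loose <- sens$n_parents[sens$pc_alpha == 0.3]
  expect_true(all(n_loose >= n_tight))
  # the planted driver survives screening at both levels
  expect_true(all(grepl("X\\(-1\\)", sens$parents[sens$region == "Y"])))
})

test_that("configuration guards reject invalid settings", {
  expect_error(pcmci_config(alpha = 0), "alpha")
  expect_error(pcmci_config(tau_max = 0), "tau_max")
  expect_s3_class(pcmci_config(ci_method = "GPDC"), "pcmci_config")
})
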