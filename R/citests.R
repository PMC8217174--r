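# Conditional-independence tests and the block-shuffle permutation engine.
# Three statistics share one interface: linear partial correlation (PC),
# distance correlation of Gaussian-process regression residuals (GPDC), and
# k-nearest-neighbor conditional mutual information (CMIknn). Significance
# always comes from permutations that shuffle contiguous blocks of one
# series, so temporal autocorrelation is respected under the null.

ci_result <- function(method, statistic, p_value, n_effective,
                      condition_set = NULL, block_len = NA_integer_,
                      n_perm = NA_integer_, fallback = FALSE) {
  stopifnot(is.finite(statistic), p_value > 0, p_value <= 1)
  structure(list(method = method, statistic = statistic, p_value = p_value,
                 n_effective = n_effective, condition_set = condition_set,
                 block_len = block_len, n_perm = n_perm, fallback = fallback),
            class = "ci_test_result")
}

#' @export
print.ci_test_result <- function(x, ...) {
  cat(sprintf("%s test: statistic %.4f, p = %.4g (n = %d, %d permutations, block length %d)\n",
              x$method, x$statistic, x$p_value, x$n_effective, x$n_perm,
              x$block_len))
  invisible(x)
}

#' Default permutation block length from the autocorrelation decay
#'
#' The smallest lag at which the mean absolute autocorrelation across the
#' supplied channels falls below `2/sqrt(n)`, clamped to `[1, n/20]`.
#'
#' @param M Numeric matrix (samples x channels) or vector.
#' @return Integer block length.
#' @export
default_block_len <- function(M) {
  M <- as.matrix(M)
  n <- nrow(M)
  lag_max <- max(1L, min(n - 1L, floor(n / 20), 50L))
  ac <- sapply(seq_len(ncol(M)), function(j) {
    a <- acf(M[, j], lag.max = lag_max, plot = FALSE)$acf[-1]
    abs(a)
  })
  ac <- as.matrix(ac)
  m <- rowMeans(ac)
  hit <- which(m < 2 / sqrt(n))
  bl <- if (length(hit)) hit[1] else lag_max
  max(1L, min(as.integer(bl), floor(n / 20)))
}

# Index matrix (n x n_perm) of block permutations. Contiguous blocks of
# block_len are permuted; when 0-based segment boundaries are given, blocks
# are formed and permuted within each segment so no shuffled chunk crosses a
# concatenation junction.
make_block_perms <- function(n, block_len, n_perm, boundaries = NULL) {
  if (is.null(boundaries)) boundaries <- 0L
  cpp_block_perms(as.integer(n), as.integer(block_len), as.integer(n_perm),
                  as.integer(boundaries))
}

p_from_perm <- function(observed, perm_stats) {
  (1 + sum(abs(perm_stats) >= abs(observed))) / (length(perm_stats) + 1)
}

#' Block-shuffle permutation p-value for an arbitrary statistic
#'
#' Cuts `x` into contiguous blocks of `block_len`, permutes the block order
#' (`y` and `Z` fixed), recomputes the statistic for each permutation, and
#' returns the two-sided permutation p-value
#' `(1 + #\{|perm| >= |observed|\}) / (n_perm + 1)`.
#'
#' @param statistic_fn Function `(x, y, Z) -> numeric` (for `y`/`Z` `NULL`
#'   it is called with `NULL`).
#' @param x Numeric vector that gets shuffled.
#' @param y,Z Held fixed; passed through to `statistic_fn`.
#' @param n_perm Number of permutations.
#' @param block_len Block length; default from [default_block_len()] on `x`.
#'   Must not exceed `n/4`.
#' @param seed Optional integer seed for the permutations.
#' @param boundaries Optional 0-based segment starts that permuted blocks may
#'   not cross.
#' @return The p-value, with attributes `observed` and `perm_stats`.
#' @export
block_shuffle_pvalue <- function(statistic_fn, x, y = NULL, Z = NULL,
                                 n_perm = 500L, block_len = NULL,
                                 seed = NULL, boundaries = NULL) {
  n <- length(x)
  if (is.null(block_len)) block_len <- default_block_len(x)
  if (block_len < 1 || block_len > n / 4) {
    stop(sprintf("block_len %d outside [1, n/4] = [1, %d]: degenerate shuffle",
                 as.integer(block_len), floor(n / 4)), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  observed <- statistic_fn(x, y, Z)
  perms <- make_block_perms(n, block_len, n_perm, boundaries)
  perm_stats <- vapply(seq_len(n_perm),
                       function(p) statistic_fn(x[perms[, p]], y, Z),
                       numeric(1))
  p <- p_from_perm(observed, perm_stats)
  attr(p, "observed") <- observed
  attr(p, "perm_stats") <- perm_stats
  p
}

# Orthonormal basis of [1, Z] with rank-deficient columns dropped (warned).
resid_basis <- function(Z, n) {
  X <- cbind(`(Intercept)` = rep(1, n), Z)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    warning("rank-deficient conditioning set; dropping column(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
}

#' Linear partial-correlation test (PC)
#'
#' Removes the linear influence of the conditioning set `Z` from both `x`
#' and `y` by ordinary least squares (with intercept) and computes the
#' Pearson correlation of the residuals; with empty `Z` this is the plain
#' correlation. The two-sided p-value comes from the block-shuffle
#' permutation engine (the permuted series is re-residualized each time).
#'
#' @param x,y Numeric vectors of equal length.
#' @param Z Optional numeric matrix of conditioning columns (may be `NULL`).
#' @param n_perm Number of block permutations.
#' @param block_len Permutation block length; `NULL` for the autocorrelation
#'   rule of [default_block_len()].
#' @param seed Optional seed.
#' @param boundaries Optional 0-based concatenation boundaries the
#'   permutations must respect.
#' @return A `ci_test_result`.
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(300); y <- 0.5 * x + rnorm(300)
#' parcorr(x, y, n_perm = 99, seed = 1)
parcorr <- function(x, y, Z = NULL, n_perm = 500L, block_len = NULL,
                    seed = NULL, boundaries = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (!is.null(Z)) Z <- as.matrix(Z)
  nz <- if (is.null(Z)) 0L else ncol(Z)
  if (n < nz + 10) {
    stop(sprintf("n = %d too small for %d conditioning columns", n, nz),
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  Q <- resid_basis(Z, n)
  rx <- x - Q %*% crossprod(Q, x)
  ry <- drop(y - Q %*% crossprod(Q, y))
  safe_cor <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0) return(0)
    cor(a, b)
  }
  observed <- safe_cor(drop(rx), ry)
  if (is.null(block_len)) {
    block_len <- default_block_len(cbind(x, y))
  }
  if (block_len < 1 || block_len > n / 4) {
    stop(sprintf("block_len %d outside [1, n/4]: degenerate shuffle",
                 as.integer(block_len)), call. = FALSE)
  }
  perms <- make_block_perms(n, block_len, n_perm, boundaries)
  Xp <- matrix(x[perms], n, n_perm)
  # residuals are orthogonal to the intercept, so correlations reduce to
  # crossproducts of mean-zero columns
  Rxp <- Xp - Q %*% crossprod(Q, Xp)
  ssy <- sum(ry^2)
  ssx <- colSums(Rxp^2)
  denom <- sqrt(ssx * ssy)
  perm_stats <- rep(0, n_perm)
  ok <- denom > 0
  perm_stats[ok] <- drop(crossprod(Rxp, ry))[ok] / denom[ok]
  ci_result("PC", observed, p_from_perm(observed, perm_stats), n,
            condition_set = Z, block_len = as.integer(block_len),
            n_perm = as.integer(n_perm))
}

#' Gaussian-process regression / distance-correlation test (GPDC)
#'
#' `x` and `y` are each regressed on `Z` by Gaussian-process regression
#' ([gp_regress()]); the statistic is the distance correlation between the
#' two residual series, which detects non-linear dependence. With empty `Z`
#' the regression step is skipped. Significance: the x-residual series is
#' block-shuffled and the distance correlation recomputed per permutation
#' (the statistic is nonnegative, so the two-sided rule reduces to the upper
#' tail).
#'
#' @inheritParams parcorr
#' @param m_max Training-point cap for the GP fit (see [gp_regress()]).
#' @return A `ci_test_result`; `fallback` is `TRUE` when a failed GP fit was
#'   replaced by linear residualization.
#' @export
gpdc <- function(x, y, Z = NULL, n_perm = 500L, block_len = NULL,
                 seed = NULL, boundaries = NULL, m_max = 300L) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (!is.null(Z)) Z <- as.matrix(Z)
  nz <- if (is.null(Z)) 0L else ncol(Z)
  if (n < nz + 10) {
    stop(sprintf("n = %d too small for %d conditioning columns", n, nz),
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  xs <- drop(scale(x))
  ys <- drop(scale(y))
  fallback <- FALSE
  if (nz > 0) {
    res <- tryCatch({
      list(rx = gp_regress(Z, xs, m_max)$residuals,
           ry = gp_regress(Z, ys, m_max)$residuals)
    }, error = function(e) NULL)
    if (is.null(res)) {
      warning("GP fit failed; falling back to linear residualization",
              call. = FALSE)
      fallback <- TRUE
      Q <- resid_basis(Z, n)
      res <- list(rx = drop(xs - Q %*% crossprod(Q, xs)),
                  ry = drop(ys - Q %*% crossprod(Q, ys)))
    }
    rx <- res$rx
    ry <- res$ry
  } else {
    rx <- xs
    ry <- ys
  }
  observed <- cpp_dcor(rx, ry)
  if (is.null(block_len)) block_len <- default_block_len(cbind(x, y))
  if (block_len < 1 || block_len > n / 4) {
    stop(sprintf("block_len %d outside [1, n/4]: degenerate shuffle",
                 as.integer(block_len)), call. = FALSE)
  }
  perms <- make_block_perms(n, block_len, n_perm, boundaries)
  perm_stats <- cpp_dcor_perm(rx, ry, perms)
  ci_result("GPDC", observed, p_from_perm(observed, perm_stats), n,
            condition_set = Z, block_len = as.integer(block_len),
            n_perm = as.integer(n_perm), fallback = fallback)
}

#' k-nearest-neighbor conditional mutual information test (CMIknn)
#'
#' Estimates `I(x; y | Z)` in nats with a KSG-style nearest-neighbor
#' estimator (Chebyshev metric, per-column standardization); the reported
#' statistic is clipped at 0. Significance comes from the block-shuffle
#' engine by default, matching the other tests; a
#' nearest-neighbor-respecting local permutation scheme (x values swapped
#' among neighbors in Z space, applicable when `Z` is non-empty) is
#' available via `perm = "local"`, but it ignores temporal autocorrelation
#' and over-rejects on autocorrelated series.
#'
#' @inheritParams parcorr
#' @param k Number of nearest neighbors of the estimator (default 10).
#' @param perm `"block"` (default) or `"local"`.
#' @param kperm Neighborhood size of the local permutation scheme.
#' @return A `ci_test_result`.
#' @export
cmiknn <- function(x, y, Z = NULL, k = 10L, n_perm = 500L, block_len = NULL,
                   seed = NULL, boundaries = NULL,
                   perm = c("block", "local"), kperm = 5L) {
  perm <- match.arg(perm)
  n <- length(x)
  stopifnot(length(y) == n, k >= 3)
  if (!is.null(Z)) Z <- as.matrix(Z)
  nz <- if (is.null(Z)) 0L else ncol(Z)
  if (n < nz + 10) {
    stop(sprintf("n = %d too small for %d conditioning columns", n, nz),
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  std <- function(v) {
    s <- sd(v)
    if (s == 0) s <- 1
    (v - mean(v)) / s
  }
  xm <- matrix(std(x), ncol = 1)
  ym <- matrix(std(y), ncol = 1)
  zm <- if (nz > 0) apply(Z, 2, std) else matrix(0, n, 0)
  zm <- matrix(zm, nrow = n)
  has_dup <- anyDuplicated(xm) || anyDuplicated(ym) ||
    (nz > 0 && anyDuplicated(zm))
  if (has_dup) {
    message("duplicate points detected; applying jitter at 1e-10 scale")
    xm <- xm + rnorm(n) * 1e-10
    ym <- ym + rnorm(n) * 1e-10
    if (nz > 0) zm <- zm + matrix(rnorm(n * nz), n, nz) * 1e-10
  }
  observed <- max(0, cpp_cmi_knn(xm, ym, zm, as.integer(k)))
  use_local <- perm == "local" && nz > 0
  if (use_local) {
    nbrs <- cpp_knn_indices(zm, as.integer(kperm))
    perms <- cpp_local_perm(nbrs, as.integer(n_perm))
    block_len <- NA_integer_
  } else {
    if (is.null(block_len)) block_len <- default_block_len(cbind(x, y))
    if (block_len < 1 || block_len > n / 4) {
      stop(sprintf("block_len %d outside [1, n/4]: degenerate shuffle",
                   as.integer(block_len)), call. = FALSE)
    }
    perms <- make_block_perms(n, block_len, n_perm, boundaries)
  }
  perm_stats <- pmax(0, cpp_cmi_knn_perm(xm, ym, zm, as.integer(k), perms))
  ci_result("CMIknn", observed, p_from_perm(observed, perm_stats), n,
            condition_set = Z,
            block_len = if (use_local) NA_integer_ else as.integer(block_len),
            n_perm = as.integer(n_perm))
}

#' Uniform interface to the three conditional-independence tests
#'
#' Dispatches on `method` and optionally caches results on disk, keyed by a
#' hash of the data, method and options (useful for CMIknn, whose cost
#' dominates full-graph runs).
#'
#' @param x,y Numeric vectors.
#' @param Z Optional conditioning matrix.
#' @param method `"PC"`, `"GPDC"` or `"CMIknn"`.
#' @param options Named list of method options (`n_perm`, `block_len`,
#'   `seed`, `boundaries`, `k`, `kperm`, `perm`, `m_max`, `cache_dir`).
#' @return A `ci_test_result`.
#' @export
ci_test <- function(x, y, Z = NULL, method = c("PC", "GPDC", "CMIknn"),
                    options = list()) {
  method <- match.arg(method)
  cache_dir <- options$cache_dir
  options$cache_dir <- NULL
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
    tf <- tempfile()
    saveRDS(list(x, y, Z, method, options), tf)
    key <- unname(tools::md5sum(tf))
    unlink(tf)
    cache_file <- file.path(cache_dir, paste0(key, ".rds"))
    if (file.exists(cache_file)) return(readRDS(cache_file))
  }
  args <- c(list(x = x, y = y, Z = Z), options)
  res <- switch(method,
    PC = do.call(parcorr, args[names(args) %in%
      c("x", "y", "Z", "n_perm", "block_len", "seed", "boundaries")]),
    GPDC = do.call(gpdc, args[names(args) %in%
      c("x", "y", "Z", "n_perm", "block_len", "seed", "boundaries", "m_max")]),
    CMIknn = do.call(cmiknn, args[names(args) %in%
      c("x", "y", "Z", "k", "n_perm", "block_len", "seed", "boundaries",
        "perm", "kperm")])
  )
  if (!is.null(cache_dir)) saveRDS(res, cache_file)
  res
}
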