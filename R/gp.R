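# Gaussian-process regression used by the GPDC conditional-independence
# test: isotropic squared-exponential kernel plus a noise term, inputs
# standardized, hyperparameters fit by maximizing the log marginal
# likelihood. For large n a deterministic subset-of-data approximation keeps
# the fit at O(m^3) with m capped.

sq_dist <- function(A, B = A) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

gp_nll <- function(theta, D2, y) {
  ell2 <- exp(2 * theta[1])
  sf2 <- exp(2 * theta[2])
  sn2 <- exp(2 * theta[3])
  m <- length(y)
  K <- sf2 * exp(-0.5 * D2 / ell2)
  diag(K) <- diag(K) + sn2 + 1e-8
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  alpha <- backsolve(ch, forwardsolve(t(ch), y))
  0.5 * sum(y * alpha) + sum(log(diag(ch))) + 0.5 * m * log(2 * pi)
}

#' Gaussian-process regression of a response on conditioning variables
#'
#' Fits `y ~ f(Z)` with a squared-exponential kernel plus observation noise.
#' Inputs are standardized internally; hyperparameters (length-scale, signal
#' variance, noise variance) maximize the log marginal likelihood. For
#' `n > m_max` training points a deterministic thinning to `m_max` points is
#' used as the fit/prediction basis (subset-of-data approximation).
#'
#' @param Z Numeric matrix of predictors (n x d).
#' @param y Numeric response vector.
#' @param m_max Cap on the number of training points used in the fit.
#' @return List with `fitted` (posterior mean at all n inputs), `residuals`,
#'   and `theta` (log hyperparameters).
#' @export
gp_regress <- function(Z, y, m_max = 300L) {
  Z <- as.matrix(Z)
  n <- length(y)
  stopifnot(nrow(Z) == n)
  zs <- apply(Z, 2, sd)
  zs[zs == 0] <- 1
  Zs <- sweep(sweep(Z, 2, colMeans(Z)), 2, zs, "/")
  mu <- mean(y)
  sy <- sd(y)
  if (sy == 0) sy <- 1
  ys <- (y - mu) / sy
  idx <- if (n > m_max) unique(round(seq(1, n, length.out = m_max))) else seq_len(n)
  Zt <- Zs[idx, , drop = FALSE]
  yt <- ys[idx]
  D2 <- sq_dist(Zt)
  fit <- optim(c(0, 0, log(0.3)), gp_nll, D2 = D2, y = yt,
               method = "L-BFGS-B", lower = log(1e-3), upper = log(1e3),
               control = list(maxit = 50))
  theta <- fit$par
  ell2 <- exp(2 * theta[1])
  sf2 <- exp(2 * theta[2])
  sn2 <- exp(2 * theta[3])
  K <- sf2 * exp(-0.5 * D2 / ell2)
  diag(K) <- diag(K) + sn2 + 1e-8
  ch <- chol(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), yt))
  Ks <- sf2 * exp(-0.5 * sq_dist(Zs, Zt) / ell2)
  pred <- drop(Ks %*% alpha)
  fitted <- mu + sy * pred
  list(fitted = fitted, residuals = y - fitted, theta = theta)
}
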