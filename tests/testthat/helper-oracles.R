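# Independent oracles used across the suite.

# Stationary covariance of a VAR(1) process x_t = A x_{t-1} + e_t,
# cov(e) = Q, via the discrete Lyapunov equation vec(S) = (I - A (x) A)^-1 vec(Q).
var1_stationary_cov <- function(A, Q) {
  p <- nrow(A)
  vecS <- solve(diag(p^2) - kronecker(A, A), as.vector(Q))
  matrix(vecS, p, p)
}

# Correlation of (x_i at t-1, x_j at t) for the VAR(1) above:
# cov(x_{t-1}, x_t) = S t(A), so cov(x_i,{t-1}, x_j,t) = (S t(A))[i, j].
var1_lag1_cor <- function(A, Q, i, j) {
  S <- var1_stationary_cov(A, Q)
  C <- S %*% t(A)
  C[i, j] / sqrt(S[i, i] * S[j, j])
}

# Partial correlation of columns i and j given columns `cond`, from the
# inverse of the covariance matrix.
partial_cor_oracle <- function(S, i, j, cond) {
  idx <- c(i, j, cond)
  P <- solve(S[idx, idx, drop = FALSE])
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# Matrix of independent AR(1) channels.
ar1_channels <- function(n, p, phi = 0.3, seed = 1) {
  set.seed(seed)
  m <- sapply(seq_len(p), function(j) as.numeric(arima.sim(list(ar = phi), n)))
  colnames(m) <- paste0("R", seq_len(p))
  m
}

# FFT amplitude of a series at the frequency bin nearest f_hz.
fft_amplitude <- function(x, f_hz, dt) {
  n <- length(x)
  sp <- Mod(fft(x))[1:(n %/% 2)]
  freqs <- (0:(n %/% 2 - 1)) / (n * dt)
  sp[which.min(abs(freqs - f_hz))]
}

# Minimal causal_graph stub for classification tests.
make_graph <- function(links, method, condition, regions) {
  if (nrow(links)) {
    links$statistic <- links$statistic %||% rep(0.5, nrow(links))
    links$p_value <- links$p_value %||% rep(0.005, nrow(links))
  }
  structure(list(links = links, all_tests = links, parents = NULL,
                 method = method, alpha = 0.01, tau_max = 2,
                 condition = condition, regions = regions),
            class = "causal_graph")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

link_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(source = r[[1]], target = r[[2]], lag = as.integer(r[[3]]),
               statistic = if (length(r) >= 4) as.numeric(r[[4]]) else 0.5,
               p_value = if (length(r) >= 5) as.numeric(r[[5]]) else 0.005,
               stringsAsFactors = FALSE)
  }))
}

empty_links <- function() {
  data.frame(source = character(0), target = character(0), lag = integer(0),
             statistic = numeric(0), p_value = numeric(0),
             stringsAsFactors = FALSE)
}
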