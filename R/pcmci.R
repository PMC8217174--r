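# Two-stage causal discovery: (1) iterative condition (parent) selection per
# region, (2) momentary conditional independence (MCI) tests for every
# lagged ordered pair and every contemporaneous unordered pair, conditioning
# on the selected parents. Lag-0 links are reported undirected because the
# sampling interval cannot resolve their orientation.

#' Configuration of the causal-discovery run
#'
#' @param alpha Two-sided significance level for reported links (default
#'   0.01).
#' @param tau_max Maximum lag in samples (default 2; at a 1.6 s repetition
#'   time this is a 3.2 s causal horizon).
#' @param pc_alpha Looser level used during parent selection (default 0.2).
#' @param ci_method Conditional-independence test of the MCI stage: `"PC"`,
#'   `"GPDC"` or `"CMIknn"`.
#' @param max_conds Cap on the number of conditions taken from each parent
#'   set in the MCI stage (default 3).
#' @param n_perm Permutations per MCI-stage test (default 500).
#' @param n_perm_pc Permutations per parent-selection test (default 49: the
#'   screening decision is at `pc_alpha` = 0.2, so a p-value resolution of
#'   1/50 is ample and the stage dominates runtime otherwise).
#' @param block_len Permutation block length; `NULL` for the autocorrelation
#'   rule.
#' @param k,kperm CMIknn estimator and local-permutation neighborhood sizes.
#' @param cmiknn_perm `"block"` (default) or `"local"` permutation scheme
#'   for CMIknn; the block shuffle respects temporal autocorrelation.
#' @param m_max GP training-point cap for GPDC.
#' @param seed Integer seed; per-link permutation seeds are derived from it
#'   and the link labels, so results are invariant to column order.
#' @param parent_method Test used during parent selection (default `"PC"`,
#'   regardless of `ci_method`, for tractability).
#' @param cache_dir Optional on-disk cache directory for test results.
#' @return Object of class `pcmci_config`.
#' @export
pcmci_config <- function(alpha = 0.01, tau_max = 2L, pc_alpha = 0.2,
                         ci_method = c("PC", "GPDC", "CMIknn"),
                         max_conds = 3L, n_perm = 500L, n_perm_pc = 49L,
                         block_len = NULL,
                         k = 10L, kperm = 5L,
                         cmiknn_perm = c("block", "local"), m_max = 300L,
                         seed = 1L, parent_method = "PC",
                         cache_dir = NULL) {
  ci_method <- match.arg(ci_method)
  cmiknn_perm <- match.arg(cmiknn_perm)
  stopifnot(alpha > 0, alpha < 1, tau_max >= 1, pc_alpha > 0, pc_alpha < 1,
            max_conds >= 0, n_perm >= 1, n_perm_pc >= 1,
            1 / (n_perm_pc + 1) < pc_alpha)
  structure(list(alpha = alpha, tau_max = as.integer(tau_max),
                 pc_alpha = pc_alpha, ci_method = ci_method,
                 max_conds = as.integer(max_conds),
                 n_perm = as.integer(n_perm),
                 n_perm_pc = as.integer(n_perm_pc), block_len = block_len,
                 k = as.integer(k), kperm = as.integer(kperm),
                 cmiknn_perm = cmiknn_perm, m_max = as.integer(m_max),
                 seed = as.integer(seed), parent_method = parent_method,
                 cache_dir = cache_dir),
            class = "pcmci_config")
}

# Deterministic per-test seed from the run seed and a label-based key, so a
# permutation of the input columns permutes the results identically.
link_seed <- function(seed, key) {
  u <- utf8ToInt(key)
  h <- sum(u * seq_along(u)) %% 20011L
  (as.integer(seed) %% 99991L) * 20011L + h
}

series_values <- function(series) {
  if (inherits(series, "multichannel_series")) series$values else as.matrix(series)
}

series_boundaries <- function(series) {
  if (inherits(series, "multichannel_series")) series$boundaries else 0L
}

# Column of region `i` at lag `lag`, aligned so sample t runs over
# (offset+1):n of the original series.
lagged_col <- function(values, i, lag, offset) {
  n <- nrow(values)
  values[(offset + 1 - lag):(n - lag), i]
}

aligned_boundaries <- function(boundaries, offset, n_eff) {
  b <- boundaries - offset
  c(0L, b[b > 0 & b < n_eff])
}

entry_key <- function(region, lag) paste0(region, "@", lag)

# Build the conditioning matrix for a set of (region, lag) entries.
cond_matrix <- function(values, regions, entries, offset) {
  if (is.null(entries) || nrow(entries) == 0L) return(NULL)
  keep <- !duplicated(entry_key(entries$region, entries$lag))
  entries <- entries[keep, , drop = FALSE]
  Z <- sapply(seq_len(nrow(entries)), function(r) {
    lagged_col(values, match(entries$region[r], regions), entries$lag[r],
               offset)
  })
  Z <- matrix(Z, ncol = nrow(entries))
  colnames(Z) <- entry_key(entries$region, entries$lag)
  Z
}

test_options <- function(config, seed, boundaries) {
  switch(config$ci_method,
    PC = list(n_perm = config$n_perm, block_len = config$block_len,
              seed = seed, boundaries = boundaries,
              cache_dir = config$cache_dir),
    GPDC = list(n_perm = config$n_perm, block_len = config$block_len,
                seed = seed, boundaries = boundaries, m_max = config$m_max,
                cache_dir = config$cache_dir),
    CMIknn = list(n_perm = config$n_perm, block_len = config$block_len,
                  seed = seed, boundaries = boundaries, k = config$k,
                  kperm = config$kperm, perm = config$cmiknn_perm,
                  cache_dir = config$cache_dir))
}

#' Stage 1: iterative parent selection per region
#'
#' For each region, all lagged candidates `(i, tau)`, `tau = 1..tau_max`
#' (including the autodependency), are screened by conditional-independence
#' tests conditioned on the `q` strongest other surviving candidates for
#' `q = 0, 1, 2, ...`; candidates with `p > pc_alpha` at any level are
#' removed, until the set stabilizes. The partial-correlation test is used
#' by default (see `parent_method`).
#'
#' @param series A `multichannel_series` or samples x regions matrix.
#' @param config A [pcmci_config()].
#' @return Object of class `parent_set`: a named list (one entry per region)
#'   of data frames with columns `region`, `lag`, `stat`, ordered by
#'   decreasing `|stat|`.
#' @export
select_parents <- function(series, config = pcmci_config()) {
  values <- series_values(series)
  regions <- colnames(values)
  if (is.null(regions)) regions <- paste0("R", seq_len(ncol(values)))
  n <- nrow(values)
  offset <- config$tau_max
  n_eff <- n - offset
  bnd <- aligned_boundaries(series_boundaries(series), offset, n_eff)
  out <- list()
  for (j in seq_along(regions)) {
    y <- lagged_col(values, j, 0L, offset)
    cands <- expand.grid(i = seq_along(regions), tau = seq_len(config$tau_max))
    cands$region <- regions[cands$i]
    cands$stat <- NA_real_
    run_test <- function(src_i, src_tau, Z) {
      x <- lagged_col(values, src_i, src_tau, offset)
      key <- paste("pc1", regions[j], regions[src_i], src_tau,
                   if (is.null(Z)) 0 else ncol(Z))
      parcorr(x, y, Z, n_perm = config$n_perm_pc,
              block_len = config$block_len,
              seed = link_seed(config$seed, key), boundaries = bnd)
    }
    # level q = 0: unconditional screening
    keep <- logical(nrow(cands))
    for (r in seq_len(nrow(cands))) {
      res <- run_test(cands$i[r], cands$tau[r], NULL)
      cands$stat[r] <- res$statistic
      keep[r] <- res$p_value <= config$pc_alpha
    }
    cands <- cands[keep, , drop = FALSE]
    cands <- cands[order(-abs(cands$stat), cands$region, cands$tau), ,
                   drop = FALSE]
    q <- 1L
    while (q <= nrow(cands) - 1L) {
      keep <- logical(nrow(cands))
      newstat <- cands$stat
      for (r in seq_len(nrow(cands))) {
        others <- cands[-r, , drop = FALSE]
        conds <- data.frame(region = others$region[seq_len(q)],
                            lag = others$tau[seq_len(q)],
                            stringsAsFactors = FALSE)
        Z <- cond_matrix(values, regions, conds, offset)
        res <- run_test(cands$i[r], cands$tau[r], Z)
        newstat[r] <- res$statistic
        keep[r] <- res$p_value <= config$pc_alpha
      }
      cands$stat <- newstat
      cands <- cands[keep, , drop = FALSE]
      cands <- cands[order(-abs(cands$stat), cands$region, cands$tau), ,
                     drop = FALSE]
      q <- q + 1L
    }
    out[[regions[j]]] <- data.frame(region = cands$region, lag = cands$tau,
                                    stat = cands$stat,
                                    stringsAsFactors = FALSE)
  }
  structure(out, class = "parent_set")
}

#' @export
print.parent_set <- function(x, ...) {
  for (j in names(x)) {
    p <- x[[j]]
    if (nrow(p) == 0) {
      cat(sprintf("%s: (no parents)\n", j))
    } else {
      cat(sprintf("%s: %s\n", j,
                  paste(sprintf("%s(-%d)", p$region, p$lag), collapse = ", ")))
    }
  }
  invisible(x)
}

cap_parents <- function(p, max_conds, drop_key = NULL) {
  if (is.null(p) || nrow(p) == 0L) return(p[0, , drop = FALSE])
  if (!is.null(drop_key)) {
    p <- p[entry_key(p$region, p$lag) != drop_key, , drop = FALSE]
  }
  p <- p[order(-abs(p$stat)), , drop = FALSE]
  utils::head(p, max_conds)
}

#' Stage 2: momentary conditional independence test for one link
#'
#' For a lagged link `source -> target` at lag `tau >= 1`, tests the lagged
#' source against the target conditioned on the target's parents (minus the
#' link itself) and the source's parents shifted by `tau`. For a
#' contemporaneous link (`tau = 0`), conditions on the lagged parents of
#' both endpoints. Each parent set contributes at most `max_conds` strongest
#' entries.
#'
#' @param series A `multichannel_series` or matrix.
#' @param source,target Region labels.
#' @param lag Integer lag in `0..tau_max`.
#' @param parents A `parent_set` from [select_parents()].
#' @param config A [pcmci_config()].
#' @return A `ci_test_result`.
#' @export
mci_link_test <- function(series, source, target, lag, parents,
                          config = pcmci_config()) {
  values <- series_values(series)
  regions <- colnames(values)
  if (is.null(regions)) regions <- paste0("R", seq_len(ncol(values)))
  if (lag > config$tau_max) {
    stop(sprintf("link lag %d exceeds tau_max %d", lag, config$tau_max),
         call. = FALSE)
  }
  offset <- 2L * config$tau_max
  n <- nrow(values)
  n_eff <- n - offset
  bnd <- aligned_boundaries(series_boundaries(series), offset, n_eff)
  i <- match(source, regions)
  j <- match(target, regions)
  if (is.na(i) || is.na(j)) stop("unknown region label", call. = FALSE)
  x <- lagged_col(values, i, lag, offset)
  y <- lagged_col(values, j, 0L, offset)
  if (lag >= 1L) {
    pj <- cap_parents(parents[[target]], config$max_conds,
                      drop_key = entry_key(source, lag))
    pi <- cap_parents(parents[[source]], config$max_conds)
    if (nrow(pi)) pi$lag <- pi$lag + lag
    conds <- rbind(pj, pi)
  } else {
    pi <- cap_parents(parents[[source]], config$max_conds)
    pj <- cap_parents(parents[[target]], config$max_conds)
    conds <- rbind(pi, pj)
  }
  Z <- cond_matrix(values, regions, conds, offset)
  key <- paste("mci", config$ci_method, source, target, lag)
  opts <- test_options(config, link_seed(config$seed, key), bnd)
  ci_test(x, y, Z, method = config$ci_method, options = opts)
}

#' Run the full two-stage causal discovery
#'
#' Selects parents once, then applies the MCI test to every lagged ordered
#' pair of distinct regions (`tau = 1..tau_max`) and every contemporaneous
#' unordered pair. Links with `p <= alpha` are retained. Lag-0 links are
#' stored undirected with endpoints in canonical region order.
#' Autodependencies are used in conditioning but not reported.
#'
#' @param series A `multichannel_series` or samples x regions matrix.
#' @param config A [pcmci_config()].
#' @param parents Optional precomputed `parent_set` (so several MCI methods
#'   can share one selection stage).
#' @return Object of class `causal_graph`: list with `links` (data frame
#'   `source`, `target`, `lag`, `statistic`, `p_value`), `all_tests` (every
#'   test performed), `parents`, `method`, `alpha`, `condition`.
#' @export
run_pcmci <- function(series, config = pcmci_config(), parents = NULL) {
  values <- series_values(series)
  regions <- colnames(values)
  if (is.null(regions)) {
    regions <- paste0("R", seq_len(ncol(values)))
    colnames(values) <- regions
    if (!inherits(series, "multichannel_series")) series <- values
  }
  if (is.null(parents)) parents <- select_parents(series, config)
  rows <- list()
  for (tau in seq_len(config$tau_max)) {
    for (i in seq_along(regions)) {
      for (j in seq_along(regions)) {
        if (i == j) next
        res <- mci_link_test(series, regions[i], regions[j], tau, parents,
                             config)
        rows[[length(rows) + 1L]] <-
          data.frame(source = regions[i], target = regions[j], lag = tau,
                     statistic = res$statistic, p_value = res$p_value,
                     stringsAsFactors = FALSE)
      }
    }
  }
  for (i in seq_along(regions)) {
    for (j in seq_along(regions)) {
      if (i >= j) next
      res <- mci_link_test(series, regions[i], regions[j], 0L, parents,
                           config)
      rows[[length(rows) + 1L]] <-
        data.frame(source = regions[i], target = regions[j], lag = 0L,
                   statistic = res$statistic, p_value = res$p_value,
                   stringsAsFactors = FALSE)
    }
  }
  all_tests <- do.call(rbind, rows)
  links <- all_tests[all_tests$p_value <= config$alpha, , drop = FALSE]
  ord <- order(links$lag, match(links$source, regions),
               match(links$target, regions))
  links <- links[ord, , drop = FALSE]
  rownames(links) <- NULL
  condition <- if (inherits(series, "multichannel_series")) series$condition
               else NA_character_
  structure(list(links = links, all_tests = all_tests, parents = parents,
                 method = config$ci_method, alpha = config$alpha,
                 tau_max = config$tau_max, condition = condition,
                 regions = regions, config = config),
            class = "causal_graph")
}

#' Sensitivity of parent selection to the screening level
#'
#' Re-runs [select_parents()] over a grid of `pc_alpha` values and reports
#' the selected parent sets and their sizes, so the stability of the
#' condition-selection stage can be judged before committing to a full run.
#'
#' @param series A `multichannel_series` or matrix.
#' @param config A [pcmci_config()]; its `pc_alpha` is overridden by the
#'   grid.
#' @param pc_alphas Numeric vector of screening levels to try.
#' @return Data frame with one row per (pc_alpha, region): number of
#'   parents and a compact listing.
#' @export
pc_alpha_sensitivity <- function(series, config = pcmci_config(),
                                 pc_alphas = c(0.05, 0.1, 0.2, 0.3)) {
  rows <- list()
  for (a in pc_alphas) {
    cfg <- config
    cfg$pc_alpha <- a
    ps <- select_parents(series, cfg)
    for (j in names(ps)) {
      p <- ps[[j]]
      rows[[length(rows) + 1L]] <- data.frame(
        pc_alpha = a, region = j, n_parents = nrow(p),
        parents = if (nrow(p)) paste(sprintf("%s(-%d)", p$region, p$lag),
                                     collapse = ",") else "",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' @export
print.causal_graph <- function(x, ...) {
  cat(sprintf("causal graph (%s, alpha %.3g%s): %d significant link(s) of %d tested\n",
              x$method, x$alpha,
              if (is.na(x$condition)) "" else paste0(", ", x$condition),
              nrow(x$links), nrow(x$all_tests)))
  if (nrow(x$links)) {
    for (r in seq_len(nrow(x$links))) {
      l <- x$links[r, ]
      arrow <- if (l$lag == 0) "--" else "->"
      cat(sprintf("  %s %s %s  lag %d  stat %.3f  p %.4g\n",
                  l$source, arrow, l$target, l$lag, l$statistic, l$p_value))
    }
  }
  invisible(x)
}
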