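# Validation benchmarks: null calibration of the full pipeline, recovery of
# a planted linear graph, per-method power differentiation, and a frozen
# end-to-end classification fixture. These back the package's acceptance
# checks and are reusable for sensitivity analyses.

#' Null calibration of the full discovery pipeline
#'
#' Runs the two-stage discovery (partial-correlation test) on independent
#' AR(1) channels and reports the fraction of link tests declared
#' significant at `alpha`, which should match `alpha` up to binomial noise.
#'
#' @param n_seeds Number of independent replicates.
#' @param n Samples per channel.
#' @param n_regions Number of channels.
#' @param phi AR(1) coefficient of each channel.
#' @param n_perm Permutations per test.
#' @param alpha Significance level.
#' @param seed Master seed.
#' @return List with `fraction`, `n_significant`, `n_tests`, and the 99%
#'   binomial interval `ci` around `alpha`.
#' @export
benchmark_null_calibration <- function(n_seeds = 10L, n = 4000L,
                                       n_regions = 8L, phi = 0.3,
                                       n_perm = 199L, alpha = 0.01,
                                       seed = 1L) {
  regions <- if (n_regions == 8L) bg_regions() else paste0("R", seq_len(n_regions))
  n_sig <- 0L
  n_tests <- 0L
  for (s in seq_len(n_seeds)) {
    b <- generate_block(regions, list(), n, autocorr = phi,
                        seed = seed * 1000L + s)
    cfg <- pcmci_config(alpha = alpha, n_perm = n_perm, seed = seed + s)
    g <- run_pcmci(b, cfg)
    n_sig <- n_sig + nrow(g$links)
    n_tests <- n_tests + nrow(g$all_tests)
  }
  ci <- qbinom(c(0.005, 0.995), n_tests, alpha) / n_tests
  list(fraction = n_sig / n_tests, n_significant = n_sig, n_tests = n_tests,
       ci = ci)
}

#' The planted five-link linear benchmark graph
#'
#' Five directed lagged couplings with strengths spanning 0.4-0.7, stable
#' together with the default autoregression.
#'
#' @return List of [coupling()] objects.
#' @export
recovery_links <- function() {
  list(coupling("M1", "Put", 1, "linear", 0.4),
       coupling("Put", "GPe", 1, "linear", 0.5),
       coupling("GPe", "STN", 2, "linear", 0.6),
       coupling("STN", "GPi", 1, "linear", 0.7),
       coupling("SN", "Tal", 2, "linear", 0.45))
}

#' Recovery of a planted linear graph
#'
#' Simulates the five-link linear system of [recovery_links()] at length
#' `n`, runs the full discovery with the partial-correlation test, and
#' scores recovery (fraction of planted links found) and the
#' false-discovery proportion of the reported graph.
#'
#' @inheritParams benchmark_null_calibration
#' @return List with `recovery` and `fdp` (means over seeds) plus the
#'   per-seed vectors.
#' @export
benchmark_recovery <- function(n_seeds = 10L, n = 4000L, n_perm = 199L,
                               alpha = 0.01, seed = 1L) {
  links <- recovery_links()
  gt <- ground_truth(links)
  rec <- numeric(n_seeds)
  fdp <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    b <- generate_block(bg_regions(), links, n, autocorr = 0.3,
                        seed = seed * 1000L + s)
    cfg <- pcmci_config(alpha = alpha, n_perm = n_perm, seed = seed + s)
    g <- run_pcmci(b, cfg)
    found <- vapply(links, function(cp) {
      any(g$links$source == cp$source & g$links$target == cp$target &
            g$links$lag == cp$lag)
    }, logical(1))
    rec[s] <- mean(found)
    if (nrow(g$links) == 0L) {
      fdp[s] <- 0
    } else {
      true_link <- vapply(seq_len(nrow(g$links)), function(r) {
        gt_has_link(gt, g$links$source[r], g$links$target[r], g$links$lag[r])
      }, logical(1))
      fdp[s] <- mean(!true_link)
    }
  }
  list(recovery = mean(rec), fdp = mean(fdp), per_seed_recovery = rec,
       per_seed_fdp = fdp)
}

#' Per-method power on non-linear and multiplicative dependence
#'
#' Two scenarios: (1) a quadratic dependence `y = x^2 + noise` at
#' `n = n_quad`, where the distance-correlation test should reject and the
#' partial-correlation test should not; (2) pure multiplicative noise
#' `y = x * eps` at `n = n_mult`, the density-structured dependence the
#' CMI test targets. Returns per-method rejection rates at the 1% level.
#'
#' @param n_seeds_quad,n_quad Replicates and sample size for the quadratic
#'   scenario.
#' @param n_seeds_mult,n_mult Replicates and sample size for the
#'   multiplicative scenario.
#' @param n_perm Permutations for PC/GPDC; the CMI test uses
#'   `n_perm_cmi`.
#' @param n_perm_cmi Permutations for the CMI test (its cost dominates).
#' @param seed Master seed.
#' @return List of rates: `quad_gpdc_not_pc`, `quad_gpdc`, `quad_pc`,
#'   `mult_pc`, `mult_gpdc`, `mult_cmiknn`.
#' @export
benchmark_method_differentiation <- function(n_seeds_quad = 50L,
                                             n_quad = 1000L,
                                             n_seeds_mult = 12L,
                                             n_mult = 2000L,
                                             n_perm = 99L,
                                             n_perm_cmi = 99L,
                                             seed = 1L) {
  q_gp <- q_pc <- q_joint <- 0L
  for (s in seq_len(n_seeds_quad)) {
    set.seed(seed * 10000L + s)
    x <- rnorm(n_quad)
    y <- x^2 + 0.5 * rnorm(n_quad)
    p_pc <- parcorr(x, y, n_perm = n_perm, seed = seed + s)$p_value
    p_gp <- gpdc(x, y, n_perm = n_perm, seed = seed + s)$p_value
    if (p_gp <= 0.01) q_gp <- q_gp + 1L
    if (p_pc <= 0.01) q_pc <- q_pc + 1L
    if (p_gp <= 0.01 && p_pc > 0.01) q_joint <- q_joint + 1L
  }
  m_pc <- m_gp <- m_cmi <- 0L
  for (s in seq_len(n_seeds_mult)) {
    set.seed(seed * 20000L + s)
    x <- rnorm(n_mult)
    y <- x * rnorm(n_mult)
    if (parcorr(x, y, n_perm = n_perm, seed = seed + s)$p_value <= 0.01)
      m_pc <- m_pc + 1L
    if (gpdc(x, y, n_perm = n_perm, seed = seed + s)$p_value <= 0.01)
      m_gp <- m_gp + 1L
    if (cmiknn(x, y, n_perm = n_perm_cmi, seed = seed + s)$p_value <= 0.01)
      m_cmi <- m_cmi + 1L
  }
  list(quad_gpdc_not_pc = q_joint / n_seeds_quad,
       quad_gpdc = q_gp / n_seeds_quad,
       quad_pc = q_pc / n_seeds_quad,
       mult_pc = m_pc / n_seeds_mult,
       mult_gpdc = m_gp / n_seeds_mult,
       mult_cmiknn = m_cmi / n_seeds_mult)
}

#' Ground truth of the end-to-end classification fixture
#'
#' Five regions with one planted link per taxonomy cell: an instantaneous
#' linear pair, a lagged quadratic link (source kept free of parents and
#' lag-0 partners, so no induced partial-linear signal leaks into the
#' linear test), a lagged multiplicative-noise link, and one
#' condition-specific linear link per condition.
#'
#' @return Named list of [ground_truth()] objects (`motor`, `resting`).
#' @export
fixture_graphs <- function() {
  shared <- list(coupling("M1", "SN", 0, "linear", 0.6),
                 coupling("Put", "GPe", 1, "quadratic", 0.7),
                 coupling("SN", "Tal", 1, "multiplicative_noise", 1.5))
  list(
    motor = ground_truth(c(shared,
                           list(coupling("M1", "Tal", 1, "linear", 0.5))),
                         condition = "motor"),
    resting = ground_truth(c(shared,
                             list(coupling("M1", "GPe", 2, "linear", 0.5))),
                           condition = "resting"))
}

#' End-to-end classification fixture
#'
#' Generates a reduced two-condition study (4 subjects x 1 block x 200
#' volumes, five regions) from [fixture_graphs()], runs the full pipeline
#' (preprocessing, then discovery with all three tests sharing one
#' parent-selection stage), and classifies the links.
#'
#' @param seed Master seed.
#' @param n_perm Permutations for PC/GPDC.
#' @param n_perm_cmi Permutations for the CMI test.
#' @return List with `classified` (a `classified_links`), `graphs` (nested
#'   per condition/method), `ground_truth`, and `expected` (planted links
#'   with their expected timing/nature/persistence labels).
#' @export
classification_fixture <- function(seed = 1L, n_perm = 199L,
                                   n_perm_cmi = 99L) {
  regions <- c("M1", "Put", "GPe", "SN", "Tal")
  gts <- fixture_graphs()
  design <- study_design(n_subjects = 4, blocks_per_condition = 1,
                         block_length = 200)
  study <- generate_study(design, gts, seed = seed, regions = regions)
  series <- preprocess_study(study)
  graphs <- list()
  for (cond in names(series)) {
    parents <- NULL
    for (m in c("PC", "GPDC", "CMIknn")) {
      np <- if (m == "CMIknn") n_perm_cmi else n_perm
      cfg <- pcmci_config(ci_method = m, n_perm = np, seed = seed)
      g <- run_pcmci(series[[cond]], cfg, parents = parents)
      parents <- g$parents
      graphs[[cond]][[m]] <- g
    }
  }
  expected <- data.frame(
    source = c("M1", "Put", "SN", "M1", "M1"),
    target = c("SN", "GPe", "Tal", "Tal", "GPe"),
    lag = c(0L, 1L, 1L, 1L, 2L),
    timing = c("instantaneous", "single-delayed", "single-delayed",
               "single-delayed", "double-delayed"),
    nature = c("linear", "non-linear", "complex", "linear", "linear"),
    persistence = c("permanent", "permanent", "permanent", "motor-only",
                    "resting-only"),
    stringsAsFactors = FALSE)
  list(classified = classify_links(graphs), graphs = graphs,
       ground_truth = gts, expected = expected)
}
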