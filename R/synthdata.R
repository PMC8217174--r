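# Synthetic multichannel generator: autoregressive channels with planted
# lagged/contemporaneous couplings of several functional forms, organised in
# the block/subject layout of a two-condition fMRI study, plus the matching
# ground-truth causal graph.

#' Specify a planted coupling between two regions
#'
#' A coupling adds a term driven by the source region to the target region's
#' process. Four functional forms are available: `linear`
#' (`strength * x`), `quadratic` (`strength * x^2`), `threshold`
#' (`strength * sign(x - offset)`), and `multiplicative_noise`
#' (`strength * x * eps` with `eps` standard normal, a dependence with no
#' additive signal that only density-based tests detect). Couplings at lag 0
#' are realised as a shared latent innovation injected into both regions, so
#' the generative direction is unobservable; ground truth records them
#' undirected.
#'
#' @param source,target Region labels.
#' @param lag Integer lag in samples, `0` to a small maximum (typically 2).
#' @param kind One of `"linear"`, `"quadratic"`, `"threshold"`,
#'   `"multiplicative_noise"`.
#' @param strength Real coefficient. The linear part of the full coupling set
#'   must keep the companion matrix stable (spectral radius < 1).
#' @param offset Center of the step for `kind = "threshold"`.
#' @return An object of class `coupling`.
#' @export
#' @examples
#' coupling("M1", "Put", lag = 1, kind = "linear", strength = 0.5)
coupling <- function(source, target, lag, kind = "linear", strength = 0.5,
                     offset = 0) {
  kind <- match.arg(kind,
                    c("linear", "quadratic", "threshold", "multiplicative_noise"))
  stopifnot(is.character(source), is.character(target),
            length(lag) == 1L, lag >= 0, lag == round(lag),
            is.numeric(strength), length(strength) == 1L, is.finite(strength))
  if (lag == 0 && kind != "linear") {
    stop("lag-0 couplings are shared-innovation terms and must be linear",
         call. = FALSE)
  }
  structure(list(source = source, target = target, lag = as.integer(lag),
                 kind = kind, strength = strength, offset = offset),
            class = "coupling")
}

#' @export
print.coupling <- function(x, ...) {
  arrow <- if (x$lag == 0) "--" else "->"
  cat(sprintf("%s %s %s  lag %d  %s  strength %.3g\n",
              x$source, arrow, x$target, x$lag, x$kind, x$strength))
  invisible(x)
}

#' Ground-truth causal graph for one condition
#'
#' Wraps a set of [coupling()] records so planted links can be compared with
#' recovered ones. Lag-0 entries compare equal regardless of orientation.
#'
#' @param couplings List of [coupling()] objects (a single coupling is
#'   accepted).
#' @param condition Condition label the graph applies to.
#' @return Object of class `ground_truth`, with an `as.data.frame` method.
#' @export
ground_truth <- function(couplings, condition = "resting") {
  if (inherits(couplings, "coupling")) couplings <- list(couplings)
  stopifnot(all(vapply(couplings, inherits, logical(1), "coupling")))
  structure(list(couplings = couplings, condition = condition),
            class = "ground_truth")
}

#' @export
as.data.frame.ground_truth <- function(x, ...) {
  do.call(rbind, lapply(x$couplings, function(cp) {
    data.frame(source = cp$source, target = cp$target, lag = cp$lag,
               kind = cp$kind, strength = cp$strength,
               stringsAsFactors = FALSE)
  }))
}

#' Test whether a link is present in a ground-truth graph
#'
#' Lag-0 links match in either orientation (the generative direction of a
#' shared-innovation coupling is unobservable).
#'
#' @param gt A [ground_truth()] object.
#' @param source,target Region labels.
#' @param lag Integer lag.
#' @return Logical scalar.
#' @export
gt_has_link <- function(gt, source, target, lag) {
  stopifnot(inherits(gt, "ground_truth"))
  for (cp in gt$couplings) {
    if (cp$lag != lag) next
    if (cp$source == source && cp$target == target) return(TRUE)
    if (lag == 0 && cp$source == target && cp$target == source) return(TRUE)
  }
  FALSE
}

#' Block/subject layout of a two-condition study
#'
#' Defaults mirror a study of 20 subjects scanned in four alternating blocks
#' of 100 volumes (two motor, two resting) at a repetition time of 1.6 s, so
#' each subject contributes 400 volumes and each condition concatenates to
#' 20 x 2 x 100 = 4000 samples.
#'
#' @param n_subjects Number of subjects.
#' @param blocks_per_condition Blocks per subject and condition.
#' @param block_length Volumes per block.
#' @param repetition_time Sampling interval in seconds.
#' @param conditions Condition labels.
#' @return Object of class `study_design`.
#' @export
#' @examples
#' d <- study_design()
#' d$n_subjects * d$blocks_per_condition * d$block_length  # samples/condition
study_design <- function(n_subjects = 20L, blocks_per_condition = 2L,
                         block_length = 100L, repetition_time = 1.6,
                         conditions = c("motor", "resting")) {
  stopifnot(n_subjects >= 1, blocks_per_condition >= 1, block_length >= 10,
            repetition_time > 0, length(conditions) >= 1,
            !anyDuplicated(conditions))
  structure(list(n_subjects = as.integer(n_subjects),
                 blocks_per_condition = as.integer(blocks_per_condition),
                 block_length = as.integer(block_length),
                 repetition_time = repetition_time,
                 conditions = conditions),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf(
    "study design: %d subjects x %d blocks x %d volumes per condition (%s); TR %.3g s\n",
    x$n_subjects, x$blocks_per_condition, x$block_length,
    paste(x$conditions, collapse = ", "), x$repetition_time))
  cat(sprintf("volumes per subject: %d\n",
              x$block_length * x$blocks_per_condition * length(x$conditions)))
  invisible(x)
}

# Companion matrix of the linear part (autoregression + linear lagged
# couplings); its spectral radius must be < 1 for stationarity.
companion_radius <- function(regions, couplings, autocorr) {
  n <- length(regions)
  lags <- c(1L, vapply(couplings, function(cp) cp$lag, integer(1)))
  p <- max(lags)
  A <- vector("list", p)
  for (l in seq_len(p)) A[[l]] <- matrix(0, n, n)
  diag(A[[1]]) <- autocorr
  for (cp in couplings) {
    if (cp$kind == "linear" && cp$lag >= 1) {
      i <- match(cp$source, regions)
      j <- match(cp$target, regions)
      A[[cp$lag]][j, i] <- A[[cp$lag]][j, i] + cp$strength
    }
  }
  comp <- matrix(0, n * p, n * p)
  for (l in seq_len(p)) comp[1:n, ((l - 1) * n + 1):(l * n)] <- A[[l]]
  if (p > 1) {
    comp[(n + 1):(n * p), 1:(n * (p - 1))] <- diag(n * (p - 1))
  }
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Generate one block of coupled multichannel series
#'
#' Each region follows an autoregressive innovation process; planted
#' couplings add lagged terms of the specified kind, and lag-0 couplings add
#' a shared latent innovation to both endpoints. A burn-in period is
#' discarded so the returned block is a stationary realisation.
#'
#' @param regions Character vector of region labels.
#' @param couplings List of [coupling()] objects (may be empty).
#' @param block_length Number of samples returned; at least 10.
#' @param noise_scale Standard deviation of each region's own innovation.
#' @param autocorr Lag-1 autoregressive coefficient, scalar or one per
#'   region.
#' @param seed Integer seed; identical seeds give identical blocks.
#' @param innovations `"gaussian"` (default) or `"uniform"` (variance
#'   matched).
#' @param burn_in Samples discarded before the block starts.
#' @return `block_length` x `length(regions)` numeric matrix with region
#'   labels as column names.
#' @export
#' @examples
#' b <- generate_block(c("X", "Y"),
#'                     list(coupling("X", "Y", 1, "linear", 0.6)),
#'                     block_length = 200, seed = 1)
generate_block <- function(regions, couplings = list(), block_length,
                           noise_scale = 1, autocorr = 0.3, seed,
                           innovations = c("gaussian", "uniform"),
                           burn_in = 100L) {
  regions <- check_regions(regions)
  innovations <- match.arg(innovations)
  if (inherits(couplings, "coupling")) couplings <- list(couplings)
  stopifnot(block_length >= 10, !missing(seed))
  n <- length(regions)
  if (length(autocorr) == 1L) autocorr <- rep(autocorr, n)
  stopifnot(length(autocorr) == n)
  for (cp in couplings) {
    if (!(cp$source %in% regions) || !(cp$target %in% regions)) {
      stop("unknown region label in coupling: ", cp$source, " -> ", cp$target,
           call. = FALSE)
    }
  }
  rad <- companion_radius(regions, couplings, autocorr)
  if (rad >= 1) {
    stop(sprintf(
      "unstable coupling set: companion-matrix spectral radius %.3f >= 1", rad),
      call. = FALSE)
  }
  set.seed(seed)
  total <- block_length + burn_in
  innov <- if (innovations == "gaussian") {
    matrix(rnorm(total * n, sd = noise_scale), total, n)
  } else {
    matrix(runif(total * n, -sqrt(3) * noise_scale, sqrt(3) * noise_scale),
           total, n)
  }
  # shared latent innovations realise lag-0 couplings symmetrically
  mult_eps <- list()
  for (idx in seq_along(couplings)) {
    cp <- couplings[[idx]]
    if (cp$lag == 0) {
      eta <- rnorm(total)
      i <- match(cp$source, regions)
      j <- match(cp$target, regions)
      innov[, i] <- innov[, i] + cp$strength * eta
      innov[, j] <- innov[, j] + cp$strength * eta
    } else if (cp$kind == "multiplicative_noise") {
      mult_eps[[as.character(idx)]] <- rnorm(total)
    }
  }
  x <- matrix(0, total, n)
  maxlag <- max(c(1L, vapply(couplings, function(cp) cp$lag, integer(1))))
  for (t in seq_len(total)) {
    row <- innov[t, ]
    if (t > 1) row <- row + autocorr * x[t - 1, ]
    if (t > maxlag || t > 1) {
      for (idx in seq_along(couplings)) {
        cp <- couplings[[idx]]
        if (cp$lag == 0 || t <= cp$lag) next
        i <- match(cp$source, regions)
        j <- match(cp$target, regions)
        xs <- x[t - cp$lag, i]
        term <- switch(cp$kind,
          linear = cp$strength * xs,
          quadratic = cp$strength * xs^2,
          threshold = cp$strength * sign(xs - cp$offset),
          multiplicative_noise =
            cp$strength * xs * mult_eps[[as.character(idx)]][t])
        row[j] <- row[j] + term
      }
    }
    x[t, ] <- row
  }
  out <- x[(burn_in + 1):total, , drop = FALSE]
  colnames(out) <- regions
  out
}

# Deterministic per-block seed: a counter scheme, so adding subjects or
# conditions at the end never changes the seeds of earlier blocks.
block_seed <- function(master, subject, cond_index, block,
                       n_cond, blocks_per_condition) {
  counter <- ((subject - 1L) * n_cond + (cond_index - 1L)) *
    blocks_per_condition + (block - 1L)
  (as.integer(master) %% 1000000L) * 1000L + counter %% 1000L
}

#' Generate a full synthetic study
#'
#' Emits one block per subject x condition x block index, tagged with its
#' provenance, and carries the per-condition ground-truth graphs. Per-block
#' seeds are derived from the master seed by a counter scheme so the series
#' of any given subject is unchanged when more subjects are added.
#'
#' @param design A [study_design()].
#' @param graphs Named list with one [ground_truth()] per condition in
#'   `design$conditions`.
#' @param seed Master integer seed.
#' @param regions Region labels; default [bg_regions()].
#' @param noise_scale,autocorr,innovations Passed to [generate_block()].
#' @return Object of class `synth_study`: a list with elements `design`,
#'   `regions`, `graphs`, `seed` and `blocks` (each block a list with
#'   `values`, `subject`, `condition`, `block`).
#' @export
generate_study <- function(design, graphs, seed, regions = bg_regions(),
                           noise_scale = 1, autocorr = 0.3,
                           innovations = "gaussian") {
  stopifnot(inherits(design, "study_design"))
  missing_cond <- setdiff(design$conditions, names(graphs))
  if (length(missing_cond)) {
    stop("missing ground-truth graph for condition(s): ",
         paste(missing_cond, collapse = ", "), call. = FALSE)
  }
  blocks <- list()
  n_cond <- length(design$conditions)
  for (s in seq_len(design$n_subjects)) {
    for (ci in seq_along(design$conditions)) {
      cond <- design$conditions[ci]
      for (b in seq_len(design$blocks_per_condition)) {
        bs <- block_seed(seed, s, ci, b, n_cond, design$blocks_per_condition)
        vals <- generate_block(regions, graphs[[cond]]$couplings,
                               design$block_length, noise_scale, autocorr,
                               seed = bs, innovations = innovations)
        blocks[[length(blocks) + 1L]] <-
          list(values = vals, subject = s, condition = cond, block = b)
      }
    }
  }
  structure(list(design = design, regions = regions, graphs = graphs,
                 seed = as.integer(seed), blocks = blocks),
            class = "synth_study")
}

#' @export
print.synth_study <- function(x, ...) {
  cat(sprintf("synthetic study: %d blocks (%d subjects, %s), %d regions\n",
              length(x$blocks), x$design$n_subjects,
              paste(x$design$conditions, collapse = "/"), length(x$regions)))
  invisible(x)
}

#' Add a shared nuisance component to every block
#'
#' Emulates physiological signals (respiration, cardiac activity) common to
#' all regions: every region of every block gains `weight * nuisance`
#' additively. The original series are recoverable by regression on the
#' returned nuisance series.
#'
#' @param study A `synth_study`.
#' @param nuisance Numeric vector of length `design$block_length`; if `NULL`,
#'   a smooth AR(1) series (coefficient 0.9) is drawn using `seed`.
#' @param weight Scalar weight of the shared component.
#' @param seed Seed used only when `nuisance` is `NULL`.
#' @return The study with contaminated blocks and a `nuisance` element.
#' @export
add_nuisance <- function(study, nuisance = NULL, weight = 1, seed = 1L) {
  stopifnot(inherits(study, "synth_study"))
  bl <- study$design$block_length
  if (is.null(nuisance)) {
    set.seed(seed)
    nuisance <- as.numeric(stats::arima.sim(list(ar = 0.9), bl))
  }
  if (length(nuisance) != bl) {
    stop(sprintf("nuisance length %d does not match block length %d",
                 length(nuisance), bl), call. = FALSE)
  }
  study$blocks <- lapply(study$blocks, function(b) {
    b$values <- b$values + weight * nuisance
    b
  })
  study$nuisance <- nuisance
  study$nuisance_weight <- weight
  study
}

#' Write a synthetic study to disk
#'
#' One TSV per block (`sub-<k>_<condition>_block-<b>.tsv`, header row of
#' region labels), the ground truth as JSON, and a manifest JSON tying files
#' to the design.
#'
#' @param study A `synth_study`.
#' @param dir Output directory (created if needed).
#' @param digits Significant digits used when formatting values.
#' @return Invisibly, the manifest as a list.
#' @export
write_study <- function(study, dir, digits = 6) {
  stopifnot(inherits(study, "synth_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  meta <- list()
  for (b in study$blocks) {
    fn <- sprintf("sub-%d_%s_block-%d.tsv", b$subject, b$condition, b$block)
    write_matrix_tsv(b$values, file.path(dir, fn), digits = digits)
    files <- c(files, fn)
    meta[[length(meta) + 1L]] <- list(file = fn, subject = b$subject,
                                      condition = b$condition, block = b$block)
  }
  gt <- lapply(study$graphs, function(g) {
    lapply(g$couplings, function(cp) {
      list(source = cp$source, target = cp$target, lag = cp$lag,
           kind = cp$kind, strength = cp$strength)
    })
  })
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(design = unclass(study$design), regions = study$regions,
                   seed = study$seed, blocks = meta)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
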