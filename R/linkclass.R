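# Link taxonomy: timing from the lag (instantaneous / single-delayed /
# double-delayed), nature from which test detects the link (linear if PC
# finds it; non-linear if GPDC but not PC; complex if only CMIknn), and
# persistence across conditions (permanent vs condition-specific).

timing_label <- function(lag) {
  ifelse(lag == 0, "instantaneous",
         ifelse(lag == 1, "single-delayed",
                ifelse(lag == 2, "double-delayed",
                       sprintf("%d-delayed", lag))))
}

canonical_links <- function(links, regions) {
  if (nrow(links) == 0L) return(links)
  flip <- links$lag == 0 &
    match(links$source, regions) > match(links$target, regions)
  tmp <- links$source[flip]
  links$source[flip] <- links$target[flip]
  links$target[flip] <- tmp
  links
}

#' Classify the nature of links from the three per-method graphs
#'
#' Combines graphs computed on the same series with the PC, GPDC and CMIknn
#' tests (same configuration apart from `ci_method`). A link is `linear` if
#' significant under PC (regardless of the others), `non-linear` if
#' significant under GPDC but not PC, and `complex` if significant only
#' under CMIknn. Links significant nowhere are absent.
#'
#' @param graphs Named list of `causal_graph` objects; names among `"PC"`,
#'   `"GPDC"`, `"CMIknn"`.
#' @return Data frame with one row per detected link: `source`, `target`,
#'   `lag`, `timing`, `nature`, `methods` (comma-separated supporting
#'   methods), per-method `stat_*` and `p_*` columns, and `condition`.
#' @export
classify_nature <- function(graphs) {
  stopifnot(is.list(graphs), length(graphs) >= 1L,
            all(names(graphs) %in% c("PC", "GPDC", "CMIknn")))
  conds <- unique(vapply(graphs, function(g) as.character(g$condition),
                         character(1)))
  if (length(conds) > 1L) {
    stop("graphs come from different conditions: ",
         paste(conds, collapse = ", "), call. = FALSE)
  }
  regions <- graphs[[1]]$regions
  per <- lapply(graphs, function(g) canonical_links(g$links, regions))
  keys <- unique(unlist(lapply(per, function(l) {
    if (nrow(l)) paste(l$source, l$target, l$lag, sep = "|") else character(0)
  })))
  if (length(keys) == 0L) {
    out <- data.frame(source = character(0), target = character(0),
                      lag = integer(0), timing = character(0),
                      nature = character(0), methods = character(0),
                      condition = character(0), stringsAsFactors = FALSE)
    return(out)
  }
  parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  out <- data.frame(source = parts[, 1], target = parts[, 2],
                    lag = as.integer(parts[, 3]), stringsAsFactors = FALSE)
  for (m in c("PC", "GPDC", "CMIknn")) {
    out[[paste0("stat_", m)]] <- NA_real_
    out[[paste0("p_", m)]] <- NA_real_
    if (!is.null(per[[m]]) && nrow(per[[m]])) {
      mk <- paste(per[[m]]$source, per[[m]]$target, per[[m]]$lag, sep = "|")
      idx <- match(keys, mk)
      out[[paste0("stat_", m)]] <- per[[m]]$statistic[idx]
      out[[paste0("p_", m)]] <- per[[m]]$p_value[idx]
    }
  }
  sig <- function(m) !is.na(out[[paste0("p_", m)]])
  out$methods <- apply(cbind(PC = sig("PC"), GPDC = sig("GPDC"),
                             CMIknn = sig("CMIknn")), 1, function(v) {
    paste(names(v)[v], collapse = ",")
  })
  out$nature <- ifelse(sig("PC"), "linear",
                       ifelse(sig("GPDC"), "non-linear", "complex"))
  out$timing <- timing_label(out$lag)
  out$condition <- conds
  ord <- order(out$lag, match(out$source, regions),
               match(out$target, regions))
  out <- out[ord, c("source", "target", "lag", "timing", "nature", "methods",
                    "stat_PC", "p_PC", "stat_GPDC", "p_GPDC", "stat_CMIknn",
                    "p_CMIknn", "condition")]
  rownames(out) <- NULL
  out
}

#' Classify the persistence of links across conditions
#'
#' A link (source, target, lag) significant under any method in every
#' condition is `permanent`; one significant in a single condition is tagged
#' `<condition>-only`. The classification is symmetric in the order the
#' conditions are supplied.
#'
#' @param tabs Named list of classified tables (one per condition, from
#'   [classify_nature()]).
#' @return Data frame `source`, `target`, `lag`, `persistence`.
#' @export
classify_persistence <- function(tabs) {
  stopifnot(is.list(tabs), length(tabs) >= 2L, !is.null(names(tabs)))
  keysets <- lapply(tabs, function(t) {
    if (nrow(t)) paste(t$source, t$target, t$lag, sep = "|") else character(0)
  })
  keys <- sort(unique(unlist(keysets)))
  if (length(keys) == 0L) {
    return(data.frame(source = character(0), target = character(0),
                      lag = integer(0), persistence = character(0),
                      stringsAsFactors = FALSE))
  }
  incond <- sapply(keysets, function(ks) keys %in% ks)
  incond <- matrix(incond, nrow = length(keys),
                   dimnames = list(NULL, names(tabs)))
  persistence <- apply(incond, 1, function(v) {
    if (all(v)) "permanent"
    else if (sum(v) == 1L) paste0(names(v)[v], "-only")
    else paste(names(v)[v], collapse = "+")
  })
  parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  data.frame(source = parts[, 1], target = parts[, 2],
             lag = as.integer(parts[, 3]), persistence = persistence,
             stringsAsFactors = FALSE)
}

#' Full classification of per-condition, per-method graphs
#'
#' @param graphs Nested named list: `graphs[[condition]][[method]]`, each a
#'   `causal_graph`.
#' @return Object of class `classified_links`: list with `by_condition`
#'   (classified tables including a `persistence` column), `persistence`,
#'   and `counts` (from [tabulate_counts()] per condition).
#' @export
classify_links <- function(graphs) {
  stopifnot(is.list(graphs), length(graphs) >= 1L)
  tabs <- lapply(names(graphs), function(cond) {
    t <- classify_nature(graphs[[cond]])
    t$condition <- rep(cond, nrow(t))
    t
  })
  names(tabs) <- names(graphs)
  pers <- if (length(tabs) >= 2L) classify_persistence(tabs) else NULL
  if (!is.null(pers)) {
    pk <- paste(pers$source, pers$target, pers$lag, sep = "|")
    tabs <- lapply(tabs, function(t) {
      tk <- paste(t$source, t$target, t$lag, sep = "|")
      t$persistence <- pers$persistence[match(tk, pk)]
      t
    })
  }
  structure(list(by_condition = tabs, persistence = pers,
                 counts = lapply(tabs, tabulate_counts)),
            class = "classified_links")
}

#' @export
print.classified_links <- function(x, ...) {
  for (cond in names(x$by_condition)) {
    t <- x$by_condition[[cond]]
    cat(sprintf("%s: %d link(s)\n", cond, nrow(t)))
    if (nrow(t)) {
      for (r in seq_len(nrow(t))) {
        arrow <- if (t$lag[r] == 0) "--" else "->"
        cat(sprintf("  %s %s %s  %s  %s%s\n", t$source[r], arrow,
                    t$target[r], t$timing[r], t$nature[r],
                    if (!is.null(t$persistence))
                      paste0("  [", t$persistence[r], "]") else ""))
      }
    }
  }
  invisible(x)
}

#' Summary counts by timing, nature and persistence
#'
#' Counts are exhaustive and mutually exclusive; marginal totals over any
#' dimension equal the number of classified links.
#'
#' @param tab A classified table from [classify_nature()] (optionally with a
#'   `persistence` column).
#' @return Long data frame of counts with one row per non-empty combination,
#'   plus attribute `total`.
#' @export
tabulate_counts <- function(tab) {
  dims <- list(timing = tab$timing, nature = tab$nature)
  if (!is.null(tab$persistence)) dims$persistence <- tab$persistence
  if (nrow(tab) == 0L) {
    out <- data.frame(timing = character(0), nature = character(0),
                      n = integer(0), stringsAsFactors = FALSE)
    attr(out, "total") <- 0L
    return(out)
  }
  out <- as.data.frame(table(dims), stringsAsFactors = FALSE)
  names(out)[names(out) == "Freq"] <- "n"
  out <- out[out$n > 0, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total") <- nrow(tab)
  out
}

#' Binomial screen for detection frequency
#'
#' Optional screen (off by default in the classification path) for links
#' "detected more often than expected at random": each link's number of
#' significant (method, condition) cells is compared against a
#' Bernoulli(`alpha`) null over the cells actually evaluated, upper-tail
#' binomial test.
#'
#' @param classified A `classified_links` object.
#' @param alpha Per-test significance level used in the underlying graphs.
#' @param level Screen level on the binomial p-value.
#' @return Data frame `source`, `target`, `lag`, `detections`, `cells`,
#'   `p_binom`, `pass`.
#' @export
binomial_screen <- function(classified, alpha = 0.01, level = 0.05) {
  stopifnot(inherits(classified, "classified_links"))
  tabs <- classified$by_condition
  n_cond <- length(tabs)
  keys <- unique(unlist(lapply(tabs, function(t) {
    if (nrow(t)) paste(t$source, t$target, t$lag, sep = "|") else character(0)
  })))
  if (length(keys) == 0L) {
    return(data.frame(source = character(0), target = character(0),
                      lag = integer(0), detections = integer(0),
                      cells = integer(0), p_binom = numeric(0),
                      pass = logical(0)))
  }
  parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  out <- data.frame(source = parts[, 1], target = parts[, 2],
                    lag = as.integer(parts[, 3]), stringsAsFactors = FALSE)
  out$detections <- 0L
  out$cells <- 3L * n_cond
  for (t in tabs) {
    if (!nrow(t)) next
    tk <- paste(t$source, t$target, t$lag, sep = "|")
    for (m in c("PC", "GPDC", "CMIknn")) {
      pcol <- t[[paste0("p_", m)]]
      hit <- match(keys, tk)
      out$detections <- out$detections +
        as.integer(!is.na(hit) & !is.na(pcol[hit]))
    }
  }
  out$p_binom <- vapply(seq_len(nrow(out)), function(r) {
    binom.test(out$detections[r], out$cells[r], p = alpha,
               alternative = "greater")$p.value
  }, numeric(1))
  out$pass <- out$p_binom <= level
  out
}

#' Normalize test statistics for display
#'
#' Per method (and condition, when present), every statistic is divided by
#' the maximum absolute statistic of that group, so magnitudes lie in
#' `[0, 1]`, the strongest link maps to 1 in magnitude, signs are preserved
#' and the ordering of magnitudes is unchanged.
#'
#' @param df Long data frame with columns `method`, `statistic` and
#'   optionally `condition`.
#' @return The data frame with an added `normalized` column.
#' @export
normalize_statistics <- function(df) {
  stopifnot(is.data.frame(df), all(c("method", "statistic") %in% names(df)))
  grp <- if ("condition" %in% names(df)) {
    interaction(df$method, df$condition, drop = TRUE)
  } else {
    factor(df$method)
  }
  df$normalized <- NA_real_
  for (g in levels(grp)) {
    idx <- which(grp == g)
    mx <- max(abs(df$statistic[idx]))
    if (mx == 0) {
      warning("all statistics are zero in group ", g,
              "; normalized values emitted as zeros", call. = FALSE)
      df$normalized[idx] <- 0
    } else {
      df$normalized[idx] <- df$statistic[idx] / mx
    }
  }
  df
}

#' Long-format statistic table of a classified result
#'
#' One row per link x method (significant entries only), with normalized
#' statistics per method and condition, the form of the published wide
#' matrices.
#'
#' @param classified A `classified_links` object.
#' @return Long data frame `source`, `target`, `lag`, `condition`, `method`,
#'   `statistic`, `p_value`, `normalized`.
#' @export
statistic_table <- function(classified) {
  stopifnot(inherits(classified, "classified_links"))
  rows <- list()
  for (cond in names(classified$by_condition)) {
    t <- classified$by_condition[[cond]]
    for (m in c("PC", "GPDC", "CMIknn")) {
      sc <- t[[paste0("stat_", m)]]
      pc <- t[[paste0("p_", m)]]
      sel <- !is.na(pc)
      if (!any(sel)) next
      rows[[length(rows) + 1L]] <-
        data.frame(source = t$source[sel], target = t$target[sel],
                   lag = t$lag[sel], condition = cond, method = m,
                   statistic = sc[sel], p_value = pc[sel],
                   stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(source = character(0), target = character(0),
                      lag = integer(0), condition = character(0),
                      method = character(0), statistic = numeric(0),
                      p_value = numeric(0), normalized = numeric(0)))
  }
  normalize_statistics(do.call(rbind, rows))
}

#' Wide matrix of normalized statistics for one method and lag
#'
#' Rows are response regions, columns causative regions; entries are the
#' normalized statistics of significant links (`NA` where none). Lag-0
#' entries are mirrored across the diagonal since those links are
#' undirected.
#'
#' @param stat_tab Output of [statistic_table()].
#' @param method,lag,condition Selection.
#' @param regions Region order for rows/columns.
#' @return Square numeric matrix.
#' @export
link_matrix <- function(stat_tab, method, lag, condition, regions) {
  sel <- stat_tab$method == method & stat_tab$lag == lag &
    stat_tab$condition == condition
  m <- matrix(NA_real_, length(regions), length(regions),
              dimnames = list(response = regions, causative = regions))
  t <- stat_tab[sel, , drop = FALSE]
  for (r in seq_len(nrow(t))) {
    m[t$target[r], t$source[r]] <- t$normalized[r]
    if (lag == 0) m[t$source[r], t$target[r]] <- t$normalized[r]
  }
  m
}
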