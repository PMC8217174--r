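# Readers and writers: delimited series tables with a JSON sidecar carrying
# sampling interval, block boundaries and provenance; graph edge lists as
# TSV + JSON. Numeric output uses 6 significant digits for diffability.

fmt_num <- function(x, digits = 6) formatC(x, digits = digits, format = "g")

write_matrix_tsv <- function(m, path, digits = 6) {
  df <- as.data.frame(apply(m, 2, fmt_num, digits = digits),
                      stringsAsFactors = FALSE)
  names(df) <- colnames(m)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a delimited samples x regions table
#'
#' Expects a header row of region labels; the delimiter is auto-detected
#' among tab and comma. Ragged rows, non-numeric cells and duplicate labels
#' are rejected with line numbers. The sampling interval and block
#' boundaries are taken from a JSON sidecar (`<path>.json`) when present.
#'
#' @param path Path to the TSV/CSV file.
#' @param repetition_time Sampling interval in seconds; overrides the
#'   sidecar; default 1.6 when neither is given.
#' @param condition Condition label; overrides the sidecar.
#' @return A [multichannel_series()].
#' @export
read_series_table <- function(path, repetition_time = NULL, condition = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("file has no data rows: ", path, call. = FALSE)
  delim <- if (grepl("\t", lines[1])) "\t" else ","
  header <- strsplit(lines[1], delim, fixed = TRUE)[[1]]
  if (anyDuplicated(header)) {
    stop("duplicate region labels in header (line 1): ",
         paste(unique(header[duplicated(header)]), collapse = ", "),
         call. = FALSE)
  }
  ncols <- length(header)
  body <- strsplit(lines[-1], delim, fixed = TRUE)
  widths <- lengths(body)
  if (any(widths != ncols)) {
    bad <- which(widths != ncols)[1] + 1L
    stop(sprintf("ragged row at line %d: %d fields, expected %d", bad,
                 widths[bad - 1L], ncols), call. = FALSE)
  }
  vals <- suppressWarnings(
    matrix(as.numeric(unlist(body)), ncol = ncols, byrow = TRUE))
  if (anyNA(vals)) {
    bad <- which(apply(is.na(vals), 1, any))[1] + 1L
    stop(sprintf("non-numeric cell at line %d", bad), call. = FALSE)
  }
  colnames(vals) <- header
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  tr <- repetition_time %||% meta$repetition_time %||% 1.6
  bnd <- if (!is.null(meta$boundaries)) {
    as.integer(unlist(meta$boundaries))
  } else 0L
  cond <- condition %||% meta$condition %||% NA_character_
  multichannel_series(vals, regions = header, repetition_time = tr,
                      boundaries = bnd, condition = cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a multichannel series and its JSON sidecar
#'
#' @param series A `multichannel_series`.
#' @param path Output TSV path; the sidecar goes to `<path>.json`.
#' @param provenance Optional named list recorded in the sidecar (operations
#'   applied, parameters, seed).
#' @param digits Significant digits.
#' @return Invisibly, `path`.
#' @export
write_series_table <- function(series, path, provenance = NULL, digits = 6) {
  stopifnot(inherits(series, "multichannel_series"))
  write_matrix_tsv(series$values, path, digits = digits)
  meta <- list(repetition_time = series$repetition_time,
               boundaries = series$boundaries,
               condition = series$condition,
               regions = series$regions)
  if (!is.null(provenance)) meta$provenance <- provenance
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a synthetic study back from disk
#'
#' Reads the manifest, per-block TSVs and ground truth written by
#' [write_study()].
#'
#' @param dir Directory containing `manifest.json`.
#' @return A `synth_study`.
#' @export
read_study <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dir, call. = FALSE)
  manifest <- jsonlite::read_json(mf)
  d <- manifest$design
  design <- study_design(d$n_subjects, d$blocks_per_condition,
                         d$block_length, d$repetition_time,
                         unlist(d$conditions))
  regions <- unlist(manifest$regions)
  gt_file <- file.path(dir, "ground_truth.json")
  graphs <- list()
  if (file.exists(gt_file)) {
    gt <- jsonlite::read_json(gt_file)
    graphs <- lapply(names(gt), function(cond) {
      ground_truth(lapply(gt[[cond]], function(cp) {
        coupling(cp$source, cp$target, cp$lag, cp$kind, cp$strength)
      }), condition = cond)
    })
    names(graphs) <- names(gt)
  }
  blocks <- lapply(manifest$blocks, function(b) {
    m <- read_series_table(file.path(dir, b$file))
    list(values = m$values, subject = as.integer(b$subject),
         condition = b$condition, block = as.integer(b$block))
  })
  structure(list(design = design, regions = regions, graphs = graphs,
                 seed = manifest$seed, blocks = blocks),
            class = "synth_study")
}

#' Read a causal graph from its JSON document
#'
#' @param path_json Path written by [write_graph()].
#' @return A `causal_graph` (links, method, alpha, condition, regions).
#' @export
read_graph <- function(path_json) {
  doc <- jsonlite::read_json(path_json, simplifyVector = TRUE)
  links <- doc$links
  if (is.null(links) || length(links) == 0L || nrow(as.data.frame(links)) == 0L) {
    links <- data.frame(source = character(0), target = character(0),
                        lag = integer(0), statistic = numeric(0),
                        p_value = numeric(0), stringsAsFactors = FALSE)
  } else {
    links <- as.data.frame(links, stringsAsFactors = FALSE)
    links$lag <- as.integer(links$lag)
  }
  structure(list(links = links[, c("source", "target", "lag", "statistic",
                                   "p_value")],
                 all_tests = NULL, parents = NULL, method = doc$method,
                 alpha = doc$alpha, tau_max = doc$tau_max,
                 condition = doc$condition, regions = unlist(doc$regions)),
            class = "causal_graph")
}

#' Write a causal graph as a TSV edge list and a JSON document
#'
#' Rows are stable-sorted by (lag, source, target).
#'
#' @param graph A `causal_graph`.
#' @param path_tsv,path_json Output paths (`NULL` skips either).
#' @return Invisibly, the edge-list data frame.
#' @export
write_graph <- function(graph, path_tsv = NULL, path_json = NULL) {
  stopifnot(inherits(graph, "causal_graph"))
  links <- graph$links
  links$method <- rep(graph$method, nrow(links))
  links$condition <- rep(as.character(graph$condition), nrow(links))
  links <- links[, c("source", "target", "lag", "method", "statistic",
                     "p_value", "condition")]
  if (!is.null(path_tsv)) {
    out <- links
    out$statistic <- fmt_num(out$statistic)
    out$p_value <- fmt_num(out$p_value)
    write.table(out, path_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(path_json)) {
    doc <- list(method = graph$method, alpha = graph$alpha,
                tau_max = graph$tau_max,
                condition = as.character(graph$condition),
                regions = graph$regions,
                links = links)
    jsonlite::write_json(doc, path_json, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(links)
}

#' Write a classification result (long TSV, wide matrices, JSON)
#'
#' @param classified A `classified_links` object.
#' @param dir Output directory.
#' @param regions Region order for the wide matrices.
#' @return Invisibly, the long-format statistic table.
#' @export
write_classified <- function(classified, dir, regions) {
  stopifnot(inherits(classified, "classified_links"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  st <- statistic_table(classified)
  out <- st
  out$statistic <- fmt_num(out$statistic)
  out$p_value <- fmt_num(out$p_value)
  out$normalized <- fmt_num(out$normalized)
  write.table(out, file.path(dir, "links_long.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (cond in unique(st$condition)) {
    for (lag in sort(unique(st$lag))) {
      for (m in unique(st$method[st$condition == cond & st$lag == lag])) {
        mat <- link_matrix(st, m, lag, cond, regions)
        fn <- sprintf("matrix_%s_lag%d_%s.tsv", cond, lag, m)
        df <- data.frame(response = rownames(mat),
                         apply(mat, 2, fmt_num),
                         check.names = FALSE, stringsAsFactors = FALSE)
        write.table(df, file.path(dir, fn), sep = "\t", quote = FALSE,
                    row.names = FALSE)
      }
    }
  }
  doc <- list(
    by_condition = lapply(classified$by_condition, function(t) t),
    persistence = classified$persistence,
    counts = lapply(classified$counts, function(cdf) {
      list(total = attr(cdf, "total"), table = cdf)
    })
  )
  jsonlite::write_json(doc, file.path(dir, "classification.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(st)
}
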