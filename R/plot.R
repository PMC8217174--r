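# Node-link diagram of a recovered graph, base graphics: regions on a
# circle, undirected instantaneous links as plain lines, delayed causations
# as arrows (single-delayed solid, double-delayed dashed).

#' Plot a causal graph
#'
#' @param x A `causal_graph`.
#' @param col_lag Colors for lags 0, 1, 2, ... (recycled).
#' @param ... Further arguments passed to [graphics::plot.default()].
#' @return Invisibly, `x`.
#' @export
plot.causal_graph <- function(x, col_lag = c("grey30", "firebrick",
                                             "steelblue"), ...) {
  regions <- x$regions
  n <- length(regions)
  theta <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)] + pi / 2
  px <- cos(theta)
  py <- sin(theta)
  graphics::plot(px, py, type = "n", axes = FALSE, xlab = "", ylab = "",
                 xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3), asp = 1, ...)
  l <- x$links
  for (r in seq_len(nrow(l))) {
    i <- match(l$source[r], regions)
    j <- match(l$target[r], regions)
    shrink <- 0.12
    dx <- px[j] - px[i]
    dy <- py[j] - py[i]
    len <- sqrt(dx^2 + dy^2)
    x0 <- px[i] + shrink * dx / len
    y0 <- py[i] + shrink * dy / len
    x1 <- px[j] - shrink * dx / len
    y1 <- py[j] - shrink * dy / len
    colr <- col_lag[(l$lag[r] %% length(col_lag)) + 1]
    if (l$lag[r] == 0) {
      graphics::segments(x0, y0, x1, y1, col = colr, lwd = 2)
    } else {
      graphics::arrows(x0, y0, x1, y1, col = colr, lwd = 2, length = 0.1,
                       lty = if (l$lag[r] >= 2) 2 else 1)
    }
  }
  graphics::text(1.18 * px, 1.18 * py, regions)
  graphics::title(main = sprintf("%s, alpha = %.3g%s", x$method, x$alpha,
                                 if (is.na(x$condition)) ""
                                 else paste0(", ", x$condition)))
  invisible(x)
}
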