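#' UpSet-style plot of combination counts
#'
#' Base-graphics rendering of the combination lattice: bars of exclusive
#' counts over a dot matrix marking which classes each combination
#' contains. Purely an inspection aid — every quantitative surface of the
#' package is tabular.
#'
#' @param x a `CombinationCounts`.
#' @param max_bars show at most this many non-empty combinations (by
#'   descending exclusive count).
#' @param include_empty show the empty combination ("none") bar.
#' @param main plot title.
#' @param ... ignored.
#' @return Invisibly, the plotted data.frame.
#' @export
plot.CombinationCounts <- function(x, max_bars = 20,
                                   include_empty = FALSE,
                                   main = "Class combinations", ...) {
  df <- combination_table(x)
  if (!include_empty) df <- df[df$combination != "none", , drop = FALSE]
  df <- utils::head(df, max_bars)
  if (!nrow(df)) {
    warning("nothing to plot: no non-empty combinations")
    return(invisible(df))
  }
  k <- length(x$class_names)
  old <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(old))
  graphics::layout(matrix(1:2, 2), heights = c(3, 1 + 0.3 * k))
  graphics::par(mar = c(0.5, 9, 3, 1))
  bp <- graphics::barplot(df$exclusive, ylab = "cells (exclusive)",
                          main = main, col = "grey30", border = NA,
                          names.arg = rep("", nrow(df)))
  graphics::text(bp, df$exclusive, labels = df$exclusive, pos = 3,
                 cex = 0.8, xpd = NA)
  graphics::par(mar = c(1, 9, 0.5, 1))
  graphics::plot(NA, xlim = range(bp) + c(-0.6, 0.6), ylim = c(0.5, k + 0.5),
                 axes = FALSE, xlab = "", ylab = "")
  graphics::axis(2, at = seq_len(k), labels = rev(x$class_names),
                 las = 2, tick = FALSE, cex.axis = 0.9)
  for (i in seq_len(nrow(df))) {
    members <- strsplit(df$combination[i], "+", fixed = TRUE)[[1]]
    ypos <- k + 1 - match(x$class_names, x$class_names)
    on_rows <- k + 1 - match(members, x$class_names)
    graphics::points(rep(bp[i], k), ypos, pch = 21, cex = 1.3,
                     bg = "grey90", col = "grey70")
    if (df$combination[i] != "none")
      graphics::points(rep(bp[i], length(on_rows)), on_rows, pch = 21,
                       cex = 1.3, bg = "grey20", col = "grey20")
    if (length(on_rows) > 1)
      graphics::segments(bp[i], min(on_rows), bp[i], max(on_rows),
                         lwd = 2, col = "grey20")
  }
  invisible(df)
}
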