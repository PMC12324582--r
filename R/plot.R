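#' Growth-curve plot for a study
#'
#' Simple base-graphics spaghetti plot of tumor volume (log scale) versus
#' day, one line per mouse, colored by arm, with the event threshold shown
#' per mouse omitted for clarity and the volume endpoint drawn as a dashed
#' line.
#'
#' @param x An `xeno_study`.
#' @param log Use a log volume axis (zeros plotted at the detection floor).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.xeno_study <- function(x, log = TRUE, ...) {
  arms <- vapply(x$records, `[[`, character(1), "arm")
  cols <- setNames(seq_along(unique(arms)) + 1, unique(arms))
  floor_v <- max(1, x$design$detection_limit)
  allv <- unlist(lapply(x$records, function(r) pmax(r$volumes$volume, floor_v)))
  alld <- unlist(lapply(x$records, function(r) r$volumes$day))
  plot(NA, xlim = range(alld), ylim = range(c(allv, x$design$endpoint_volume)),
       xlab = "study day", ylab = expression(tumor ~ volume ~ (mm^3)),
       log = if (log) "y" else "", ...)
  for (r in x$records) {
    lines(r$volumes$day, pmax(r$volumes$volume, floor_v), col = cols[r$arm])
  }
  abline(h = x$design$endpoint_volume, lty = 2, col = "grey40")
  legend("topleft", legend = names(cols), col = cols, lty = 1, bty = "n")
  invisible(x)
}
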