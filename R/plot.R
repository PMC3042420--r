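# Base-graphics renderings of traces and I-V relationships.

#' Plot an I-V curve
#'
#' @param x An [iv_curve()].
#' @param add Add to an existing plot.
#' @param ... Passed to [graphics::plot()]/[graphics::lines()].
#' @return `x`, invisibly.
#' @export
plot.iv_curve <- function(x, add = FALSE, ...) {
  if (add) {
    graphics::lines(x$V_mV, x$I_pA, type = "b", ...)
  } else {
    graphics::plot(x$V_mV, x$I_pA, type = "b",
                   xlab = "Corrected voltage (mV)", ylab = "Current (pA)",
                   main = attr(x, "condition"), ...)
    graphics::abline(h = 0, v = 0, col = "grey70")
  }
  invisible(x)
}

#' Plot a continuous trace with bath-epoch bars
#'
#' Decimated rendering of the recorded current with the bath/blocker epochs
#' marked along the top.
#'
#' @param x A `"trace_bundle"`.
#' @param decimate Keep every `decimate`-th sample for drawing.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.trace_bundle <- function(x, decimate = 50, ...) {
  idx <- seq(1, length(x$time_s), by = decimate)
  graphics::plot(x$time_s[idx], x$current_pA[idx], type = "l",
                 xlab = "Time (s)", ylab = "Current (pA)", ...)
  bounds <- .epoch_bounds(x$meta$timeline)
  usr <- graphics::par("usr")
  y <- usr[4] - 0.03 * (usr[4] - usr[3])
  for (j in seq_len(nrow(bounds))) {
    graphics::segments(bounds$start_s[j], y, bounds$end_s[j], y, lwd = 3,
                       col = if (bounds$benzamil_uM[j] > 0) "red" else
                         "grey40")
    graphics::text((bounds$start_s[j] + bounds$end_s[j]) / 2, y,
                   bounds$label[j], pos = 3, cex = 0.7)
  }
  invisible(x)
}
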