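#' Plot a sensor layout (2D projection)
#'
#' @param x a `sensor_layout`.
#' @param adjacency optional [build_adjacency()] graph; edges are drawn.
#' @param labels draw sensor ids.
#' @param highlight optional integer indices drawn filled.
#' @param ... passed to [plot()].
#' @return invisibly, `x`.
#' @export
plot.sensor_layout <- function(x, adjacency = NULL, labels = FALSE,
                               highlight = NULL, ...) {
  plot(x$px, x$py, asp = 1, pch = 21, bg = "white",
       xlab = "", ylab = "", axes = FALSE, ...)
  if (!is.null(adjacency)) {
    A <- adjacency$matrix
    for (i in seq_len(nrow(A) - 1)) {
      js <- which(A[i, ] & seq_len(ncol(A)) > i)
      if (length(js))
        segments(x$px[i], x$py[i], x$px[js], x$py[js], col = "grey70")
    }
    points(x$px, x$py, pch = 21, bg = "white")
  }
  if (!is.null(highlight))
    points(x$px[highlight], x$py[highlight], pch = 21, bg = "firebrick")
  if (labels)
    text(x$px, x$py, x$sensor, pos = 3, cex = 0.5)
  invisible(x)
}

#' Plot an SNR spectrum
#'
#' One sensor's SNR as a function of frequency, with the noise level (1)
#' and optional target bins marked.
#'
#' @param x an `snr_spectrum`.
#' @param sensor sensor index (row) to plot.
#' @param targets optional [oddball_bins()] result.
#' @param xlim frequency range (Hz).
#' @param ... passed to [plot()].
#' @return invisibly, `x`.
#' @export
plot.snr_spectrum <- function(x, sensor = 1, targets = NULL,
                              xlim = c(0, 8), ...) {
  keep <- x$freq >= xlim[1] & x$freq <= xlim[2]
  plot(x$freq[keep], x$values[sensor, keep], type = "h",
       xlab = "frequency (Hz)", ylab = "SNR", ...)
  graphics::abline(h = 1, lty = 2, col = "grey50")
  if (!is.null(targets))
    points(targets$freqs, x$values[sensor, targets$bins], col = "firebrick",
           pch = 16)
  invisible(x)
}

#' Topographic map of a cluster test result
#'
#' Sensors are drawn at their 2D projected positions, colored by t value;
#' members of significant clusters are outlined.
#'
#' @param x a `cluster_test_result`.
#' @param layout the `sensor_layout` used for the test.
#' @param ... passed to [plot()].
#' @return invisibly, `x`.
#' @export
plot.cluster_test_result <- function(x, layout, ...) {
  tt <- x$tmap
  tt[!is.finite(tt)] <- max(tt[is.finite(tt)], 0)
  pal <- hcl.colors(64, "viridis")
  idx <- pmax(1L, pmin(64L, as.integer(
    63 * (tt - min(tt)) / max(diff(range(tt)), 1e-12)) + 1L))
  plot(layout$px, layout$py, asp = 1, pch = 21, bg = pal[idx], cex = 1.6,
       xlab = "", ylab = "", axes = FALSE, ...)
  for (cl in x$clusters) {
    if (cl$significant)
      points(layout$px[cl$members], layout$py[cl$members], pch = 1,
             cex = 2.4, lwd = 2, col = "firebrick")
  }
  invisible(x)
}
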