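#' Stacked copy-number comparison plot for a lesion pair
#'
#' Two marker-level log-ratio tracks, one above the other, with called
#' gain segments in blue and losses in red — the visual counterpart of
#' the concordance statistic.
#'
#' @param seg_a,seg_b called `segmented_profile`s of the two lesions.
#' @param main plot title.
#' @return Invisibly `NULL`; draws on the active device.
#' @export
plot_pair_profiles <- function(seg_a, seg_b, main = NULL) {
  old <- graphics::par(mfrow = c(2, 1), mar = c(2.5, 4, 2, 1))
  on.exit(graphics::par(old))
  for (seg in list(seg_a, seg_b)) {
    mk <- seg$markers
    arms <- unique(mk$arm)
    x <- seq_len(nrow(mk))
    graphics::plot(x, mk$logratio, pch = 16, cex = 0.3, col = "grey60",
                   xlab = "", ylab = "log2 ratio",
                   main = main %||% seg$lesion, xaxt = "n")
    offset <- 0
    for (a in arms) {
      n_a <- sum(mk$arm == a)
      graphics::abline(v = offset + 0.5, lty = 3, col = "grey80")
      segs <- seg$segments[seg$segments$arm == a, , drop = FALSE]
      for (i in seq_len(nrow(segs))) {
        col <- switch(segs$call[i], gain = "blue", loss = "red", "black")
        graphics::segments(offset + segs$start[i], segs$height[i],
                           offset + segs$end[i], segs$height[i],
                           col = col, lwd = 2)
      }
      offset <- offset + n_a
    }
    graphics::abline(h = seg$median, col = "grey40", lty = 2)
  }
  invisible(NULL)
}
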