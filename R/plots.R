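## Base-graphics figures for the standard outputs.

#' Plot a synchronized FRET heat map
#'
#' @param hm a [SyncHeatMap-class].
#' @param main title.
#' @importFrom graphics image abline
#' @importFrom grDevices hcl.colors
#' @export
plotHeatMap <- function(hm, main = sprintf("%s-synchronized (n = %d)",
                                           hm@anchor, hm@nTraces)) {
  image(x = hm@timeBreaks, y = hm@fretBreaks, z = t(hm@density),
        col = hcl.colors(64, "viridis"), xlab = "time (s)",
        ylab = "FRET efficiency", main = main, useRaster = TRUE)
  abline(v = 0, col = "white", lty = 2)
}

#' Plot a transition density plot
#'
#' @param td a [TDPHistogram-class].
#' @importFrom graphics image abline
#' @export
plotTDP <- function(td) {
  image(x = td@breaks, y = td@breaks, z = td@counts,
        col = hcl.colors(64, "inferno"), xlab = "E before",
        ylab = "E after",
        main = sprintf("TDP, %s %g s (%d transitions)", td@side,
                       td@windowSeconds, td@nTransitions),
        useRaster = TRUE)
  abline(0, 1, col = "grey70", lty = 2)
}

#' Plot donor/acceptor channels and FRET of one trace
#'
#' @param trace a [Trace-class].
#' @param fretTrace optional matching [FretTrace-class] to add the FRET
#'   panel and valid window.
#' @importFrom graphics plot lines par abline legend
#' @export
plotTrace <- function(trace, fretTrace = NULL) {
  op <- par(mfrow = c(if (is.null(fretTrace)) 1 else 2, 1),
            mar = c(4, 4, 1, 1))
  on.exit(par(op))
  plot(trace@time, trace@donor, type = "l", col = "darkgreen",
       xlab = "time (s)", ylab = "intensity (photons)",
       ylim = range(c(trace@donor, trace@acceptor)))
  lines(trace@time, trace@acceptor, col = "magenta")
  legend("topright", c("donor", "acceptor"), lty = 1,
         col = c("darkgreen", "magenta"), bty = "n")
  if (!is.null(fretTrace)) {
    plot(fretTrace@time, fretTrace@efficiency, type = "s",
         col = "navy", xlab = "time (s)", ylab = "FRET efficiency",
         ylim = c(-0.1, 1.1))
    vw <- fretTrace@validWindow
    if (!any(is.na(vw)))
      abline(v = fretTrace@time[vw], col = "grey60", lty = 3)
  }
}
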