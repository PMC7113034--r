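#' Plot a dual-valued amplitude profile
#'
#' Positive and negative amplitudes against atom index (model order),
#' with dashed guide lines at +/- \code{sigmaLines} map sigma.
#'
#' @param profile an \linkS4class{AmplitudeProfile}.
#' @param sigmaLines guide-line level in sigma units (default 1;
#'   0 suppresses the lines).
#' @param col2 colors for the positive and negative branch.
#' @param ... passed to \code{plot}.
#' @return invisibly, the plotted data.frame.
#' @export
plotProfile <- function(profile, sigmaLines = 1,
                        col2 = c("blue3", "goldenrod3"), ...) {
    n <- length(profile@pos)
    ylim <- range(profile@pos, profile@neg,
                  c(-1, 1) * sigmaLines * profile@mapSigma)
    graphics::plot(seq_len(n), profile@pos, type = "l", col = col2[1],
                   xlab = "atom index", ylab = "A(a_i)", ylim = ylim,
                   main = profile@label, ...)
    graphics::lines(seq_len(n), profile@neg, col = col2[2])
    graphics::abline(h = 0, col = "grey70")
    if (sigmaLines > 0)
        graphics::abline(h = c(-1, 1) * sigmaLines * profile@mapSigma,
                         lty = 2, col = "grey40")
    invisible(data.frame(index = seq_len(n), pos = profile@pos,
                         neg = profile@neg))
}

#' Heat map of a correlation matrix with block borders
#'
#' Time-ordered heat map (row 1 at the top) with optional black
#' borders around the blocks of a partition, mirroring the standard
#' presentation of time-correlation matrices with logarithmic time
#' labels.
#'
#' @param cmat a \linkS4class{CorrelationMatrix}.
#' @param blocks optional \linkS4class{BlockPartition} (square
#'   matrices only).
#' @param zlim color range (default c(-1, 1)).
#' @param ... passed to \code{graphics::image}.
#' @return invisibly, the value matrix.
#' @export
plotCorrelationMatrix <- function(cmat, blocks = NULL, zlim = c(-1, 1),
                                  ...) {
    v <- cmat@values
    nr <- nrow(v); nc <- ncol(v)
    pal <- grDevices::hcl.colors(64, "RdYlBu", rev = TRUE)
    # image() draws x right, y up; flip rows so row 1 sits on top
    graphics::image(seq_len(nc), seq_len(nr), t(v[nr:1, , drop = FALSE]),
                    col = pal, zlim = zlim, axes = FALSE,
                    xlab = "", ylab = "", ...)
    graphics::axis(1, at = seq_len(nc), labels = cmat@colLabels,
                   las = 2, cex.axis = 0.7)
    graphics::axis(2, at = seq_len(nr), labels = rev(cmat@rowLabels),
                   las = 1, cex.axis = 0.7)
    graphics::box()
    if (!is.null(blocks) && cmat@square) {
        for (b in blocks@blocks) {
            x0 <- min(b) - 0.5; x1 <- max(b) + 0.5
            graphics::rect(x0, nr - max(b) + 0.5, x1, nr - min(b) + 1.5,
                           border = "black", lwd = 2)
        }
    }
    invisible(v)
}

#' Plot region-averaged time courses
#'
#' @param series data.frame from \code{\link{regionAverage}}.
#' @param log use a logarithmic time axis (default TRUE when delays
#'   are available).
#' @param ... passed to \code{matplot}.
#' @return invisibly, the wide-format matrix plotted.
#' @export
plotRegionSeries <- function(series, log = TRUE, ...) {
    regions <- unique(series$region)
    wide <- sapply(regions, function(r)
        series$value[series$region == r])
    x <- series$delay[series$region == regions[1]]
    uselog <- log && all(is.finite(x)) && all(x > 0)
    graphics::matplot(if (uselog) x else seq_along(x), wide, type = "b",
                      pch = 16, log = if (uselog) "x" else "",
                      xlab = if (uselog) "time (s)" else "time point",
                      ylab = "normalized |A|", ...)
    graphics::legend("topleft", legend = regions, col = seq_along(regions),
                     lty = seq_along(regions), bty = "n", cex = 0.8)
    invisible(wide)
}
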