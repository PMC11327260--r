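#' Plot a reference curve with optional test curves
#'
#' Draws the pooled reference line over its observed IRSF range with a
#' band of +/- 2 replicate spreads, then overlays test grinding curves.
#'
#' @param ref a [pool_reference()] result.
#' @param tests optional named list of [fit_grinding_curve()] results.
#' @param main plot title.
#' @param spread_floor floor applied to the band half-width, as in
#'   [assess_offset()].
#' @return invisibly `NULL`; draws on the current device.
#' @export
plot_reference_curve <- function(ref, tests = NULL,
                                 main = paste("Grinding curves:", ref$species),
                                 spread_floor = 0.5) {
  xr <- ref$irsf_range
  x <- seq(xr[1], xr[2], length.out = 50)
  y <- ref$intercept + ref$slope * x
  half <- 2 * max(ref$replicate_spread, spread_floor)
  ylim <- range(y - half, y + half)
  if (!is.null(tests))
    for (tc in tests) ylim <- range(ylim, tc$points$fwhm)
  plot(NA, xlim = xr + c(-0.05, 0.05) * diff(xr), ylim = ylim,
       xlab = "IRSF", ylab = expression(paste("FWHM ", nu[3], " (", cm^-1, ")")),
       main = main)
  graphics::polygon(c(x, rev(x)), c(y - half, rev(y + half)),
                    col = grDevices::adjustcolor("grey60", 0.3), border = NA)
  graphics::lines(x, y, lwd = 2, lty = 2)
  if (!is.null(tests)) {
    cols <- grDevices::hcl.colors(max(length(tests), 2), "Dark 3")
    for (i in seq_along(tests)) {
      tc <- tests[[i]]
      o <- order(tc$points$irsf)
      graphics::lines(tc$points$irsf[o], tc$points$fwhm[o],
                      col = cols[i], lwd = 1.5)
      graphics::points(tc$points$irsf, tc$points$fwhm, col = cols[i], pch = 16)
    }
    if (!is.null(names(tests)))
      graphics::legend("topright", legend = c("reference", names(tests)),
                       col = c("black", cols[seq_along(tests)]),
                       lty = c(2, rep(1, length(tests))), cex = 0.7, bty = "n")
  }
  invisible(NULL)
}
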