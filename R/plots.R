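#' Plot a threshold sweep
#'
#' Explained variance (R^2) against the nominal SGS threshold, annotated
#' with the outlier count per threshold, on a reversed log scale so
#' stricter thresholds sit to the right.
#'
#' @param sweep a `sweep_result` from [threshold_sweep()].
#' @param ... passed to [graphics::plot()].
#' @return The sweep, invisibly.
#' @export
plot_sweep <- function(sweep, ...) {
  stopifnot(inherits(sweep, "sweep_result"))
  ok <- !sweep$empty
  x <- -log10(sweep$threshold[ok])
  y <- sweep$r_squared[ok]
  graphics::plot(x, y, type = "b", pch = 19,
                 xlab = expression(-log[10] ~ "nominal threshold"),
                 ylab = expression(R^2), ...)
  graphics::text(x, y, labels = sweep$n_loci[ok], pos = 3, cex = 0.7,
                 col = "red3")
  sig <- which(ok & !is.na(sweep$interaction_p) & sweep$interaction_p < 0.01)
  if (length(sig)) {
    graphics::points(-log10(sweep$threshold[sig]), sweep$r_squared[sig],
                     pch = 8, col = "red3")
  }
  invisible(sweep)
}

#' Contour plot of a survival surface
#'
#' Filled contours of the post-minus-pre density difference; positive
#' regions mark genotypes enriched among survivors.
#'
#' @param surface a [survival_surface()].
#' @param points optional two-column matrix of individual coordinates to
#'   overlay.
#' @param main plot title.
#' @return The surface, invisibly.
#' @export
plot_surface <- function(surface, points = NULL, main = "survival surface") {
  stopifnot(inherits(surface, "survival_surface"))
  zlim <- max(abs(surface$z))
  pal <- grDevices::colorRampPalette(c("blue3", "white", "red3"))(21)
  graphics::filled.contour(
    surface$x, surface$y, surface$z, levels = seq(-zlim, zlim, length.out = 22),
    col = pal, main = main, xlab = "PC1", ylab = "PC2",
    plot.axes = {
      graphics::axis(1); graphics::axis(2)
      graphics::contour(surface$x, surface$y, surface$z, levels = 0,
                        add = TRUE, drawlabels = FALSE)
      if (!is.null(points)) graphics::points(points, pch = 20, cex = 0.5)
    }
  )
  invisible(surface)
}

#' Scatter plot of an ANCOVA fit with per-group regression lines
#'
#' @param fit an `ancova_fit` from [ancova_interaction()].
#' @param xlab,ylab axis labels.
#' @return The fit, invisibly.
#' @export
plot_ancova <- function(fit, xlab = "covariate", ylab = "response") {
  stopifnot(inherits(fit, "ancova_fit"))
  mf <- stats::model.frame(fit$fit)
  grp <- mf$group
  cols <- grDevices::hcl.colors(nlevels(grp), "Dark 2")
  graphics::plot(mf$x, mf$y, col = cols[as.integer(grp)], pch = 19,
                 cex = 0.7, xlab = xlab, ylab = ylab)
  for (i in seq_along(fit$slopes)) {
    graphics::abline(fit$intercepts[i], fit$slopes[i], col = cols[i], lwd = 2)
  }
  graphics::legend("topleft", legend = names(fit$slopes), col = cols,
                   pch = 19, bty = "n")
  invisible(fit)
}
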