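# Base-graphics visualizations: type-colored tessellation/triangulation
# maps, probability heatmaps, and cohort parameter plots.

type_palette <- function(types)
  stats::setNames(grDevices::hcl.colors(max(3L, length(types)),
                                        "Dark 3")[seq_along(types)], types)

#' Plot a section as a type-colored tessellation or triangulation
#'
#' @param x a [fiber_section].
#' @param geometry optional precomputed [tessellation()]; computed when
#'   `style = "tessellation"` and missing.
#' @param style `"tessellation"` (type-colored Voronoi cells) or
#'   `"triangulation"` (neighbor network with type-colored centroids).
#' @param network optional `neighbor_network` for the triangulation style.
#' @param main plot title.
#' @param ... passed to [plot()].
#' @return Invisibly, the geometry or network used.
#' @export
plot.fiber_section <- function(x, geometry = NULL,
                               style = c("tessellation", "triangulation"),
                               network = NULL, main = "", ...) {
  style <- match.arg(style)
  types <- sort(unique(x$type))
  pal <- type_palette(types)
  if (style == "tessellation") {
    if (is.null(geometry)) geometry <- tessellation(x)
    plot(NA, xlim = range(geometry$boundary[, 1]),
         ylim = range(geometry$boundary[, 2]), asp = 1,
         xlab = "x", ylab = "y", main = main, ...)
    for (i in seq_along(geometry$cells))
      graphics::polygon(geometry$cells[[i]], col = pal[x$type[i]],
                        border = "grey30", lwd = 0.3)
    graphics::polygon(geometry$boundary, border = "black", lwd = 1.5)
    obj <- geometry
  } else {
    if (is.null(network)) network <- delaunay_network(x)
    plot(NA, xlim = range(x$x), ylim = range(x$y), asp = 1,
         xlab = "x", ylab = "y", main = main, ...)
    e <- network$edges
    graphics::segments(x$x[e[, 1]], x$y[e[, 1]], x$x[e[, 2]], x$y[e[, 2]],
                       col = "grey70", lwd = 0.5)
    graphics::points(x$x, x$y, pch = 19, cex = 0.5, col = pal[x$type])
    obj <- network
  }
  graphics::legend("topright", legend = types, fill = pal[types], bty = "n",
                   cex = 0.8)
  invisible(obj)
}

#' Plot a fiber-type probability surface
#'
#' Heatmap(s) of the gridded probability map with the section boundary and,
#' optionally, the fibers overlaid.
#'
#' @param x a `probability_surface`.
#' @param section optional [fiber_section] to overlay as points.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.probability_surface <- function(x, section = NULL, ...) {
  mats <- if (is.list(x$prob)) x$prob else list(prob = x$prob)
  if (length(mats) > 1L) {
    op <- graphics::par(mfrow = grDevices::n2mfrow(length(mats)))
    on.exit(graphics::par(op))
  }
  for (nm in names(mats)) {
    graphics::image(x$grid_x, x$grid_y, mats[[nm]], asp = 1, xlab = "x",
                    ylab = "y", main = nm, zlim = c(0, 1),
                    col = grDevices::hcl.colors(64, "Viridis"), ...)
    graphics::polygon(x$boundary, border = "black")
    if (!is.null(section))
      graphics::points(section$x, section$y, pch = 19, cex = 0.2,
                       col = "grey20")
  }
  invisible(x)
}

#' Scatter and box plots of cohort BMRF parameters
#'
#' @param x a `bmrf_fit_table` from [batch_fit()].
#' @param style `"scatter"` (alpha vs beta, colored by group) or
#'   `"box"` (per-parameter boxplots by group).
#' @param ... passed to the underlying plot call.
#' @return `x`, invisibly.
#' @export
plot.bmrf_fit_table <- function(x, style = c("scatter", "box"), ...) {
  style <- match.arg(style)
  tb <- x[x$ok, , drop = FALSE]
  gs <- sort(unique(tb$group))
  pal <- type_palette(gs)
  if (style == "scatter") {
    plot(tb$alpha, tb$beta, col = pal[as.character(tb$group)], pch = 19,
         xlab = expression(hat(alpha)), ylab = expression(hat(beta)), ...)
    graphics::legend("topright", legend = gs, col = pal[gs], pch = 19,
                     bty = "n")
  } else {
    op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
    graphics::boxplot(alpha ~ group, data = tb, ylab = expression(hat(alpha)), ...)
    graphics::boxplot(beta ~ group, data = tb, ylab = expression(hat(beta)), ...)
  }
  invisible(x)
}
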