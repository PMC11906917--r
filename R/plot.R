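# Plotting: head outline (circle, nose up, ears left/right), channel dots
# and interpolated topographic fields.

.draw_outline <- function(extent = 1.2) {
  plot.new()
  plot.window(c(-extent, extent), c(-extent, extent), asp = 1)
  th <- seq(0, 2 * pi, length.out = 181)
  lines(cos(th), sin(th))
  lines(c(-0.08, 0, 0.08), c(0.995, 1.08, 0.995))              # nose at 90 deg
  the <- seq(-0.35, 0.35, length.out = 25)
  lines(-cos(the) * 1.03 - 0.02, sin(the) * 0.25)              # left ear (180)
  lines(cos(the) * 1.03 + 0.02, sin(the) * 0.25)               # right ear (0)
}

#' Plot a 2D sensor layout
#'
#' Draws the head outline (unit circle, nose at the 90-degree direction,
#' ears at 0/180) with one dot per channel; channels with eccentricity > 1
#' fall outside the circle.
#'
#' @param layout a `layout_2d`.
#' @param labels draw channel labels.
#' @param ... passed to [graphics::points()].
#' @return The layout, invisibly.
#' @export
plot_layout <- function(layout, labels = FALSE, ...) {
  .draw_outline(max(1.2, max(layout$eccentricity) * 1.05))
  points(layout$x, layout$y, pch = 19, ...)
  if (labels) text(layout$x, layout$y, layout$label, pos = 3, cex = 0.6)
  invisible(layout)
}

#' @export
plot.layout_2d <- function(x, ...) plot_layout(x, ...)

#' Plot a topographic image
#'
#' @param img a `topo_image` (or `group_stat_map`, using its t raster).
#' @param ... passed to [graphics::image()].
#' @return The image object, invisibly.
#' @export
plot_topo <- function(img, ...) {
  v <- if (inherits(img, "group_stat_map")) img$t else img$values
  image(img$xgrid, img$ygrid, v, asp = 1, xlab = "", ylab = "",
        col = gray(seq(0, 1, length.out = 64)), ...)
  th <- seq(0, 2 * pi, length.out = 181)
  lines(cos(th), sin(th))
  invisible(img)
}
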