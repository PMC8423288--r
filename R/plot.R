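#' Plot a nerve sample cross section
#'
#' Base-graphics rendering of the nerve boundary and fascicle traces,
#' optionally with fiber locations overlaid.
#'
#' @param x a `nerve_sample`
#' @param fibers optional data frame with `x`, `y` columns (e.g. from
#'   [xy_locations()])
#' @param main plot title
#' @param ... passed to [graphics::plot()]
#' @export
plot.nerve_sample <- function(x, fibers = NULL, main = "nerve sample", ...) {
  allpts <- do.call(rbind, c(
    if (!is.null(x$nerve)) list(x$nerve$points),
    lapply(x$fascicles, function(f) fascicle_boundary(f)$points)))
  graphics::plot(allpts, type = "n", asp = 1, xlab = "x (um)",
                 ylab = "y (um)", main = main, ...)
  draw <- function(tr, col) graphics::polygon(tr$points, border = col)
  if (!is.null(x$nerve)) draw(x$nerve, "black")
  for (f in x$fascicles) {
    if (!is.null(f$outer)) draw(f$outer, "darkblue")
    for (inn in f$inners) draw(inn, "steelblue")
  }
  if (!is.null(fibers))
    graphics::points(fibers$x, fibers$y, pch = 20, col = "firebrick")
  invisible(x)
}
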