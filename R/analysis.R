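#' Recruitment-curve specification
#'
#' Parameters for building a population recruitment curve from a table of
#' modeled thresholds: fiber diameters are drawn per fascicle from a
#' normal distribution, rounded to the modeled diameter grid, and each
#' fiber is assigned one modeled threshold of its (fascicle, diameter)
#' drawn uniformly at random.
#'
#' @param mean,sd diameter distribution (um); defaults 8.85 and 3.1
#' @param fibers_per_fascicle population size per fascicle (default 100)
#' @param round_to diameter rounding grid (um, default 0.5)
#' @param seed RNG seed
#' @param amplitudes optional amplitude grid (mA); defaults to the sorted
#'   drawn thresholds
#' @return an object of class `recruitment_spec`
#' @export
recruitment_spec <- function(mean = 8.85, sd = 3.1,
                             fibers_per_fascicle = 100L, round_to = 0.5,
                             seed = 1L, amplitudes = NULL) {
  stopifnot(sd > 0, fibers_per_fascicle >= 1L, round_to > 0)
  structure(list(mean = mean, sd = sd,
                 fibers_per_fascicle = as.integer(fibers_per_fascicle),
                 round_to = round_to, seed = as.integer(seed),
                 amplitudes = amplitudes),
            class = "recruitment_spec")
}

#' Population recruitment curve from a threshold table
#'
#' For each fascicle, draws `fibers_per_fascicle` diameters from
#' Normal(mean, sd), rounds each to the nearest `round_to` um, clips to
#' the table's modeled diameter range (with a warning when clipping
#' occurs), assigns each drawn fiber one modeled threshold of its
#' (fascicle, rounded diameter) uniformly at random, and reports the
#' fraction of the population with threshold at or below each amplitude.
#'
#' @param thresholds data frame with columns `fascicle`, `diameter`,
#'   `threshold` (mA); several rows per (fascicle, diameter) are sampled
#'   among
#' @param spec a [recruitment_spec()]
#' @return list with `curve` (data frame `amplitude`, `fraction`),
#'   `drawn` (data frame `fascicle`, `diameter`, `threshold`), and
#'   `per_fascicle` (list of curves by fascicle)
#' @export
recruitment_curve <- function(thresholds, spec = recruitment_spec()) {
  stopifnot(inherits(spec, "recruitment_spec"),
            all(c("fascicle", "diameter", "threshold") %in%
                  names(thresholds)))
  thresholds <- thresholds[is.finite(thresholds$threshold), , drop = FALSE]
  if (!nrow(thresholds)) stop("empty threshold table")
  rng <- local_rng(spec$seed)
  dmin <- min(thresholds$diameter)
  dmax <- max(thresholds$diameter)
  fascicles <- sort(unique(thresholds$fascicle))
  drawn <- list()
  clipped <- 0L
  for (fa in fascicles) {
    tab <- thresholds[thresholds$fascicle == fa, , drop = FALSE]
    d <- with_rng(rng, stats::rnorm(spec$fibers_per_fascicle, spec$mean,
                                    spec$sd))
    d <- round(d / spec$round_to) * spec$round_to
    nclip <- sum(d < dmin | d > dmax)
    clipped <- clipped + nclip
    d <- pmin(pmax(d, dmin), dmax)
    th <- vapply(d, function(di) {
      cand <- tab$threshold[abs(tab$diameter - di) < spec$round_to / 2]
      if (!length(cand)) {
        # snap to the nearest modeled diameter present for this fascicle
        dd <- unique(tab$diameter)
        cand <- tab$threshold[tab$diameter == dd[which.min(abs(dd - di))]]
      }
      if (length(cand) == 1L) cand else
        cand[with_rng(rng, sample.int(length(cand), 1L))]
    }, 0)
    drawn[[length(drawn) + 1L]] <- data.frame(fascicle = fa, diameter = d,
                                              threshold = th)
  }
  if (clipped > 0L)
    warning(sprintf("%d drawn diameters fell outside the modeled range [%g, %g] and were clipped",
                    clipped, dmin, dmax))
  drawn <- do.call(rbind, drawn)
  amps <- spec$amplitudes %||% sort(unique(drawn$threshold))
  frac <- vapply(amps, function(a) mean(drawn$threshold <= a), 0)
  per_fas <- lapply(split(drawn, drawn$fascicle), function(dd)
    data.frame(amplitude = amps,
               fraction = vapply(amps, function(a)
                 mean(dd$threshold <= a), 0)))
  list(curve = data.frame(amplitude = amps, fraction = frac),
       drawn = drawn, per_fascicle = per_fas)
}

#' Plot-ready threshold heatmap table
#'
#' Joins fiber coordinates with their thresholds for heatmap rendering.
#' When several fibersets/placements are compared, pass the same
#' `color_range` (min/max over the union) so color scales are shared.
#'
#' @param fiberset a `fiberset`
#' @param thresholds numeric vector, one threshold (mA) per fiber in
#'   `fiberset` order
#' @return data frame with `fiber`, `x`, `y`, `fascicle`, `threshold`
#' @export
heatmap_table <- function(fiberset, thresholds) {
  if (length(thresholds) != length(fiberset$fibers))
    stop("one threshold per fiber is required")
  data.frame(
    fiber = seq_along(fiberset$fibers),
    x = vapply(fiberset$fibers, function(f) f$xy[1], 0),
    y = vapply(fiberset$fibers, function(f) f$xy[2], 0),
    fascicle = vapply(fiberset$fibers, function(f) f$fascicle, 0L),
    threshold = as.numeric(thresholds))
}

#' Render a threshold heatmap
#'
#' Scatter heatmap of per-fiber thresholds over the nerve cross section,
#' with fascicle outlines and (optionally) the cuff contact arc.
#'
#' @param table a [heatmap_table()] data frame
#' @param sample the `nerve_sample` (for outlines)
#' @param placement optional `cuff_placement` (draws the contact arc)
#' @param color_range shared color limits `c(min, max)` (mA)
#' @param file optional PNG path
#' @return the ggplot object, invisibly (requires ggplot2)
#' @export
plot_heatmap <- function(table, sample, placement = NULL,
                         color_range = range(table$threshold),
                         file = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  gg <- ggplot2::ggplot()
  outline_df <- do.call(rbind, c(
    if (!is.null(sample$nerve))
      list(data.frame(sample$nerve$points, grp = "nerve")),
    lapply(seq_along(sample$fascicles), function(i)
      data.frame(fascicle_boundary(sample$fascicles[[i]])$points,
                 grp = paste0("fascicle", i)))))
  names(outline_df)[1:2] <- c("x", "y")
  gg <- gg +
    ggplot2::geom_polygon(data = outline_df,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       group = .data$grp),
                          fill = NA, color = "grey40") +
    ggplot2::geom_point(data = table,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     color = .data$threshold), size = 3) +
    ggplot2::scale_color_viridis_c(limits = color_range,
                                   name = "threshold (mA)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_minimal()
  if (!is.null(placement)) {
    ct <- placement$cuff$contacts[[1]]
    th0 <- (ct$theta_center + placement$add_ang - ct$theta_span / 2) * pi / 180
    th1 <- (ct$theta_center + placement$add_ang + ct$theta_span / 2) * pi / 180
    th <- seq(th0, th1, length.out = 50)
    r <- placement$cuff$inner_diameter / 2
    arc <- data.frame(x = r * cos(th), y = r * sin(th))
    gg <- gg + ggplot2::geom_path(data = arc,
                                  ggplot2::aes(x = .data$x, y = .data$y),
                                  linewidth = 2)
  }
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 800, res = 120)
    print(gg)
    grDevices::dev.off()
  }
  invisible(gg)
}
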