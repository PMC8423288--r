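#' Fiber (x, y) placement modes
#'
#' Defines where fibers sit in the nerve cross section. Supported modes:
#' * `CENTROID` — one fiber per fascicle at the inner-trace centroid;
#' * `UNIFORM_COUNT` — exactly `count` fibers per fascicle, uniformly
#'   placed by seeded rejection sampling inside the inner trace;
#' * `UNIFORM_DENSITY` — per-fascicle count = `round(density * area)`,
#'   same sampler (density in fibers per mm^2);
#' * `EXPLICIT` — caller-supplied points, validated to lie inside
#'   fascicles.
#'
#' @param mode one of `"CENTROID"`, `"UNIFORM_COUNT"`, `"UNIFORM_DENSITY"`,
#'   `"EXPLICIT"`
#' @param count fibers per fascicle (`UNIFORM_COUNT`)
#' @param density fibers per mm^2 (`UNIFORM_DENSITY`)
#' @param points n x 2 matrix (`EXPLICIT`)
#' @param seed RNG seed for the stochastic modes
#' @return an object of class `fiber_xy_mode`
#' @export
fiber_xy_mode <- function(mode = c("CENTROID", "UNIFORM_COUNT",
                                   "UNIFORM_DENSITY", "EXPLICIT"),
                          count = 1L, density = NULL, points = NULL,
                          seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "UNIFORM_COUNT") stopifnot(count >= 1L)
  if (mode == "UNIFORM_DENSITY") stopifnot(!is.null(density), density > 0)
  if (mode == "EXPLICIT") stopifnot(!is.null(points))
  structure(list(mode = mode, count = as.integer(count), density = density,
                 points = points, seed = as.integer(seed)),
            class = "fiber_xy_mode")
}

#' Fiber (x, y) locations for a nerve sample
#'
#' Every returned point lies strictly inside a fascicle inner trace; fibers
#' are never placed in the epineurium. Identical seeds give identical
#' points.
#'
#' @param sample a `nerve_sample`
#' @param mode a [fiber_xy_mode()]
#' @return data frame with columns `x`, `y` (um) and `fascicle` (index of
#'   the owning fascicle)
#' @export
xy_locations <- function(sample, mode) {
  stopifnot(inherits(sample, "nerve_sample"), inherits(mode, "fiber_xy_mode"))
  inners <- unlist(lapply(seq_along(sample$fascicles), function(i)
    lapply(sample$fascicles[[i]]$inners, function(tr)
      list(fascicle = i, trace = tr))), recursive = FALSE)
  if (mode$mode == "EXPLICIT") {
    pts <- rbind(mode$points)
    fas <- integer(nrow(pts))
    for (p in seq_len(nrow(pts))) {
      hit <- which(vapply(inners, function(e)
        isTRUE(points_in_trace(pts[p, , drop = FALSE], e$trace)), TRUE))
      if (!length(hit))
        stop(sprintf("explicit point %d lies outside every fascicle inner", p))
      fas[p] <- inners[[hit[1]]]$fascicle
    }
    return(data.frame(x = pts[, 1], y = pts[, 2], fascicle = fas))
  }
  if (mode$mode == "CENTROID") {
    ctrs <- t(vapply(inners, function(e) trace_centroid(e$trace), numeric(2)))
    return(data.frame(x = ctrs[, 1], y = ctrs[, 2],
                      fascicle = vapply(inners, `[[`, 1L, "fascicle")))
  }
  rng <- local_rng(mode$seed)
  out <- list()
  zero_fas <- integer()
  for (e in inners) {
    n <- switch(mode$mode,
      UNIFORM_COUNT = mode$count,
      UNIFORM_DENSITY = {
        k <- round(mode$density * trace_area(e$trace) / 1e6)  # um^2 -> mm^2
        if (k == 0) zero_fas <- c(zero_fas, e$fascicle)
        k
      })
    if (n == 0) next
    pts <- sample_points_in_trace(e$trace, n, rng)
    out[[length(out) + 1L]] <- data.frame(x = pts[, 1], y = pts[, 2],
                                          fascicle = e$fascicle)
  }
  if (length(zero_fas))
    warning("zero fibers at the requested density in fascicle(s) ",
            paste(unique(zero_fas), collapse = ", "))
  do.call(rbind, out)
}

# seeded uniform rejection sampling over the trace's bounding box
sample_points_in_trace <- function(tr, n, rng) {
  bb <- apply(tr$points, 2, range)
  got <- matrix(numeric(0), 0, 2)
  guard <- 0L
  while (nrow(got) < n) {
    guard <- guard + 1L
    if (guard > 10000L) stop("rejection sampling failed to fill the fascicle")
    x <- runif_rng(rng, bb[1, 1], bb[2, 1])
    y <- runif_rng(rng, bb[1, 2], bb[2, 2])
    if (points_in_trace(cbind(x, y), tr)) got <- rbind(got, c(x, y))
  }
  got
}

# ---- MRG fiber geometry -----------------------------------------------------

# Published double-cable geometry anchors (McIntyre, Richardson & Grill 2002):
# columns are fiber diameter D (um), internode period deltaz, FLUT
# (paranode2) length, node/MYSA diameter, axon (FLUT/STIN) diameter, and
# myelin lamellae count. Node length 1 um and MYSA length 3 um are constant.
.mrg_anchors <- data.frame(
  D      = c(5.7, 7.3, 8.7, 10.0, 11.5, 12.8, 14.0, 15.0, 16.0),
  deltaz = c(500, 750, 1000, 1150, 1250, 1350, 1400, 1450, 1500),
  flut   = c(35, 38, 40, 46, 50, 54, 56, 58, 60),
  node_d = c(1.9, 2.4, 2.8, 3.3, 3.7, 4.2, 4.7, 5.0, 5.5),
  axon_d = c(3.4, 4.6, 5.8, 6.9, 8.1, 9.2, 10.4, 11.5, 12.7),
  nl     = c(80, 100, 110, 120, 130, 135, 140, 145, 150)
)

#' MRG myelinated fiber geometry by diameter
#'
#' Piecewise-linear interpolation of the published MRG double-cable
#' geometry anchors (5.7-16 um). Exact at the anchor diameters. Below the
#' smallest published anchor (down to 2 um) all geometric parameters are
#' scaled proportionally to diameter from the 5.7 um anchor, which keeps
#' every length positive and the internode period strictly increasing;
#' thresholds for small fibers are therefore interpolation-flavor
#' dependent.
#'
#' The repeating internode pattern is node, MYSA, FLUT, 6 x STIN, FLUT,
#' MYSA (11 compartments per period).
#'
#' @param diameter fiber diameter D (um), in [2, 16]
#' @return an object of class `mrg_geometry`: list with `diameter`,
#'   `node_length`, `mysa_length`, `flut_length`, `stin_length`,
#'   `node_diameter`, `axon_diameter`, `n_lamellae`, `deltaz` (um)
#' @export
mrg_geometry <- function(diameter) {
  if (diameter < 2 || diameter > 16)
    stop("MRG interpolation supports diameters in [2, 16] um")
  a <- .mrg_anchors
  interp <- function(col) {
    if (diameter >= a$D[1])
      stats::approx(a$D, a[[col]], xout = diameter)$y
    else
      a[[col]][1] * diameter / a$D[1]
  }
  deltaz <- interp("deltaz")
  flut <- interp("flut")
  node_len <- if (diameter >= a$D[1]) 1 else 1 * diameter / a$D[1]
  mysa_len <- if (diameter >= a$D[1]) 3 else 3 * diameter / a$D[1]
  stin <- (deltaz - node_len - 2 * mysa_len - 2 * flut) / 6
  g <- list(diameter = diameter, node_length = node_len,
            mysa_length = mysa_len, flut_length = flut,
            stin_length = stin,
            node_diameter = interp("node_d"),
            axon_diameter = interp("axon_d"),
            n_lamellae = interp("nl"),
            deltaz = deltaz)
  stopifnot(all(unlist(g) > 0),
            abs(g$deltaz - (g$node_length + 2 * g$mysa_length +
                            2 * g$flut_length + 6 * g$stin_length)) < 1e-9)
  class(g) <- "mrg_geometry"
  g
}

#' Build a fiberset: fiber locations plus compartment z grids
#'
#' For myelinated (`"MRG"`) fibers the z grid follows the 11-compartment
#' repeat (node, MYSA, FLUT, 6 x STIN, FLUT, MYSA) with compartment centers
#' as sampling coordinates; the node count is odd and, under the default
#' `"center_node"` offset policy, the middle node sits exactly at
#' `length/2 + z0`. Unmyelinated (`"RATTAY"`) fibers use uniform sections
#' of length `dz_u`.
#'
#' @param sample a `nerve_sample`
#' @param mode a [fiber_xy_mode()]
#' @param model `"MRG"` or `"RATTAY"`
#' @param diameter fiber diameter (um)
#' @param length fiber length (um); must cover at least 3 internode periods
#'   for MRG
#' @param z0 z coordinate of the fiber's proximal end (default centers the
#'   fiber on z = 0: `z0 = -length/2`)
#' @param offset_policy `"center_node"` (a node at the fiber midpoint) —
#'   the only built-in policy; kept explicit because thresholds depend on
#'   node alignment with the cuff
#' @param dz_u unmyelinated section length (um), default 8.333
#' @return an object of class `fiberset`: list with `fibers` (list of
#'   `list(xy, fascicle, model, diameter, z, compartment)`), plus the
#'   shared geometry
#' @export
build_fiberset <- function(sample, mode, model = c("MRG", "RATTAY"),
                           diameter, length, z0 = -length / 2,
                           offset_policy = "center_node", dz_u = 8.333) {
  model <- match.arg(model)
  xy <- xy_locations(sample, mode)
  zg <- fiber_z_grid(model, diameter, length, z0, dz_u)
  fibers <- lapply(seq_len(nrow(xy)), function(i)
    list(xy = c(xy$x[i], xy$y[i]), fascicle = xy$fascicle[i],
         model = model, diameter = diameter,
         z = zg$z, compartment = zg$compartment))
  structure(list(fibers = fibers, model = model, diameter = diameter,
                 length = length, z0 = z0, geometry = zg$geometry),
            class = "fiberset")
}

#' @exportS3Method base::print
print.fiberset <- function(x, ...) {
  cat(sprintf("<fiberset> %d fiber(s), %s %g um, %d compartments over %g mm\n",
              length(x$fibers), x$model, x$diameter,
              length(x$fibers[[1]]$z), x$length / 1000))
  invisible(x)
}

# compartment z coordinates (centers) and labels for one fiber
fiber_z_grid <- function(model, diameter, length, z0 = -length / 2,
                         dz_u = 8.333) {
  if (model == "RATTAY") {
    n <- floor(length / dz_u) + 1L
    z <- z0 + dz_u * (seq_len(n) - 1L)
    return(list(z = z, compartment = rep("section", n), geometry = NULL))
  }
  g <- mrg_geometry(diameter)
  if (length < 3 * g$deltaz)
    stop("fiber length must cover at least 3 internode periods")
  n_inter <- floor(length / g$deltaz)
  if (n_inter %% 2L == 1L) n_inter <- n_inter + 1L  # even internodes -> odd nodes
  n_nodes <- n_inter + 1L
  # compartment lengths of one period starting at a node
  seg_len <- c(g$node_length, g$mysa_length, g$flut_length,
               rep(g$stin_length, 6), g$flut_length, g$mysa_length)
  seg_lab <- c("node", "MYSA", "FLUT", rep("STIN", 6), "FLUT", "MYSA")
  lens <- c(rep(seg_len, n_inter), g$node_length)
  labs <- c(rep(seg_lab, n_inter), "node")
  edges <- cumsum(c(0, lens))
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  # center the middle node at z0 + length/2
  mid_node <- which(labs == "node")[(n_nodes + 1L) / 2L]
  centers <- centers - centers[mid_node] + (z0 + length / 2)
  list(z = centers, compartment = labs, geometry = g)
}
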