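#' Closed planar traces
#'
#' A `trace` is the package's primitive for a closed, simple (non
#' self-intersecting) polygon in the nerve cross-sectional plane, with
#' vertices in micrometers. Traces are normalized to counter-clockwise
#' orientation on construction. The cross section lives in the z = 0 plane
#' with the y axis up and angles measured counter-clockwise from +x.
#'
#' @param points numeric matrix (or two-column data frame) of (x, y)
#'   vertices in um; the polygon is implicitly closed (do not repeat the
#'   first vertex).
#' @param validate check simplicity and area positivity (default `TRUE`).
#' @return An object of class `trace`: a list with elements `points`
#'   (n x 2 matrix, CCW) and `closed = TRUE`.
#' @examples
#' sq <- nerve_trace(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
#' trace_area(sq)
#' @export
nerve_trace <- function(points, validate = TRUE) {
  pts <- as.matrix(points)
  storage.mode(pts) <- "double"
  if (ncol(pts) != 2L)
    stop("trace points must have two columns (x, y)")
  # drop a duplicated closing vertex if the caller supplied one
  n <- nrow(pts)
  if (n >= 2L && isTRUE(all(pts[1L, ] == pts[n, ])))
    pts <- pts[-n, , drop = FALSE]
  if (nrow(pts) < 3L)
    stop("a trace needs at least 3 vertices")
  if (anyNA(pts) || any(!is.finite(pts)))
    stop("trace vertices must be finite")
  a <- signed_area(pts)
  if (a < 0) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  if (validate) {
    if (abs(a) <= 0)
      stop("trace has zero area")
    if (!polygon_is_simple(pts))
      stop("trace is self-intersecting")
  }
  structure(list(points = pts, closed = TRUE), class = "trace")
}

#' @exportS3Method base::print
print.trace <- function(x, ...) {
  cat(sprintf("<trace> %d vertices, area %.1f um^2, centroid (%.1f, %.1f)\n",
              nrow(x$points), trace_area(x),
              trace_centroid(x)[1], trace_centroid(x)[2]))
  invisible(x)
}

is_trace <- function(x) inherits(x, "trace")

signed_area <- function(pts) {
  n <- nrow(pts)
  j <- c(2:n, 1L)
  sum(pts[, 1] * pts[j, 2] - pts[j, 1] * pts[, 2]) / 2
}

#' Polygon area of a trace (um^2)
#' @param x a `trace`
#' @return positive area in um^2 (shoelace formula)
#' @export
trace_area <- function(x) abs(signed_area(x$points))

#' Polygon centroid of a trace
#' @param x a `trace`
#' @return length-2 numeric (x, y) in um (area-weighted polygon centroid)
#' @export
trace_centroid <- function(x) {
  pts <- x$points
  n <- nrow(pts)
  j <- c(2:n, 1L)
  cr <- pts[, 1] * pts[j, 2] - pts[j, 1] * pts[, 2]
  a <- sum(cr) / 2
  cx <- sum((pts[, 1] + pts[j, 1]) * cr) / (6 * a)
  cy <- sum((pts[, 2] + pts[j, 2]) * cr) / (6 * a)
  c(cx, cy)
}

# Segment-intersection simplicity test; O(n^2) over edges, adequate for the
# vertex counts used here (~100).
polygon_is_simple <- function(pts) {
  n <- nrow(pts)
  a <- pts
  b <- pts[c(2:n, 1L), , drop = FALSE]
  for (i in seq_len(n - 2L)) {
    # skip adjacent edges (shared endpoint)
    js <- (i + 2L):n
    if (i == 1L) js <- js[js != n]
    if (!length(js)) next
    if (any(segments_intersect(a[i, ], b[i, ], a[js, , drop = FALSE],
                               b[js, , drop = FALSE])))
      return(FALSE)
  }
  TRUE
}

# vectorized proper intersection of segment (p1,p2) with segments (a[i,], b[i,])
segments_intersect <- function(p1, p2, a, b) {
  u <- p2 - p1
  d1 <- u[1] * (a[, 2] - p1[2]) - u[2] * (a[, 1] - p1[1])
  d2 <- u[1] * (b[, 2] - p1[2]) - u[2] * (b[, 1] - p1[1])
  vx <- b[, 1] - a[, 1]
  vy <- b[, 2] - a[, 2]
  d3 <- vx * (p1[2] - a[, 2]) - vy * (p1[1] - a[, 1])
  d4 <- vx * (p2[2] - a[, 2]) - vy * (p2[1] - a[, 1])
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

#' Polygonal approximation of an ellipse
#'
#' @param a,b semi-axes in um
#' @param center length-2 numeric centroid (um)
#' @param rotation rotation of the major axis, degrees CCW from +x
#' @param n_vertices number of polygon vertices (default 100; area error
#'   below 0.1 percent)
#' @return a `trace`
#' @export
ellipse_trace <- function(a, b, center = c(0, 0), rotation = 0,
                          n_vertices = 100L) {
  stopifnot(a > 0, b > 0, n_vertices >= 8L)
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  pts <- cbind(a * cos(th), b * sin(th))
  r <- rotation * pi / 180
  rot <- matrix(c(cos(r), sin(r), -sin(r), cos(r)), 2, 2)
  pts <- pts %*% t(rot)
  pts[, 1] <- pts[, 1] + center[1]
  pts[, 2] <- pts[, 2] + center[2]
  nerve_trace(pts, validate = FALSE)
}

#' Affine helpers for traces
#'
#' `trace_translate` shifts a trace; `trace_scale` scales it about a point
#' (isotropically); `trace_rotate` rotates it about a point.
#'
#' @param x a `trace`
#' @param dxy length-2 offset (um)
#' @name trace-transforms
#' @export
trace_translate <- function(x, dxy) {
  x$points[, 1] <- x$points[, 1] + dxy[1]
  x$points[, 2] <- x$points[, 2] + dxy[2]
  x
}

#' @rdname trace-transforms
#' @param factor linear scale factor
#' @param about length-2 fixed point (um)
#' @export
trace_scale <- function(x, factor, about = c(0, 0)) {
  x$points[, 1] <- about[1] + factor * (x$points[, 1] - about[1])
  x$points[, 2] <- about[2] + factor * (x$points[, 2] - about[2])
  x
}

#' @rdname trace-transforms
#' @param angle rotation angle, degrees CCW
#' @export
trace_rotate <- function(x, angle, about = c(0, 0)) {
  r <- angle * pi / 180
  dx <- x$points[, 1] - about[1]
  dy <- x$points[, 2] - about[2]
  x$points[, 1] <- about[1] + cos(r) * dx - sin(r) * dy
  x$points[, 2] <- about[2] + sin(r) * dx + cos(r) * dy
  x
}

#' Point-in-trace test
#'
#' @param pts n x 2 matrix of query points (um)
#' @param tr a `trace`
#' @return logical vector; `TRUE` for points strictly inside
#' @export
points_in_trace <- function(pts, tr) {
  pts <- rbind(pts)  # accept a bare length-2 vector
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  mgcv::in.out(rbind(tr$points, tr$points[1, ]), pts)
}

# Minimum distance from points (n x 2) to a closed polyline given by polygon
# vertices (m x 2). Vectorized point-to-segment distance.
points_to_polygon_distance <- function(pts, poly) {
  m <- nrow(poly)
  a <- poly
  b <- poly[c(2:m, 1L), , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)
  len2[len2 == 0] <- 1e-300
  dmin <- rep(Inf, nrow(pts))
  # loop over segments, vectorized over points (m ~ 100)
  for (s in seq_len(m)) {
    apx <- pts[, 1] - a[s, 1]
    apy <- pts[, 2] - a[s, 2]
    t <- (apx * ab[s, 1] + apy * ab[s, 2]) / len2[s]
    t <- pmin(1, pmax(0, t))
    dx <- apx - t * ab[s, 1]
    dy <- apy - t * ab[s, 2]
    dmin <- pmin(dmin, dx * dx + dy * dy)
  }
  sqrt(dmin)
}

#' Minimum boundary-to-boundary distance between two traces
#'
#' Distance between the polygon boundaries (0 if they touch or cross). Used
#' to enforce minimum fascicle separation.
#' @param t1,t2 `trace` objects
#' @return distance in um
#' @export
trace_boundary_distance <- function(t1, t2) {
  min(min(points_to_polygon_distance(t1$points, t2$points)),
      min(points_to_polygon_distance(t2$points, t1$points)))
}

#' Does one trace lie strictly inside another?
#'
#' `inner` is strictly inside `outer` when all its vertices are inside and
#' the boundaries keep at least `margin` um apart.
#' @param inner,outer `trace` objects
#' @param margin minimum boundary separation in um (default 0)
#' @return logical scalar
#' @export
trace_inside <- function(inner, outer, margin = 0) {
  all(points_in_trace(inner$points, outer)) &&
    trace_boundary_distance(inner, outer) >= margin
}

#' Do two traces overlap?
#'
#' Overlap means boundary crossing or one containing a vertex of the other.
#' @param t1,t2 `trace` objects
#' @return logical scalar
#' @export
traces_overlap <- function(t1, t2) {
  any(points_in_trace(t1$points, t2)) || any(points_in_trace(t2$points, t1))
}

# effective (area-equivalent) diameter of a trace, um
trace_effective_diameter <- function(x) 2 * sqrt(trace_area(x) / pi)
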