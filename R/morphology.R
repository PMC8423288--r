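#' Nerve cross-sectional morphology
#'
#' A `nerve_sample` holds the 2D cross-sectional morphology of a nerve in
#' the z = 0 plane: an optional nerve boundary trace (absent for
#' monofascicular mode) and a list of fascicles. Each fascicle has one or
#' more inner perineurium traces and an optional outer trace ("peanut"
#' fascicles carry several inners under one outer). All coordinates are um.
#'
#' @param nerve a `trace` for the nerve (epineurium) boundary, or `NULL`
#' @param fascicles list of fascicles as returned by [fascicle()]
#' @param scale um-per-pixel provenance (NA when not mask-derived)
#' @param shrinkage_applied shrinkage-correction fraction already applied
#' @param min_separation the minimum boundary separation (um) the sample was
#'   generated/validated against
#' @param validate run [validate_sample()] (default `TRUE`)
#' @return an object of class `nerve_sample`
#' @seealso [generate_mock_explicit()], [generate_mock_probabilistic()],
#'   [load_sample_masks()]
#' @export
nerve_sample <- function(nerve = NULL, fascicles = list(), scale = NA_real_,
                         shrinkage_applied = 0, min_separation = 0,
                         validate = TRUE) {
  s <- structure(list(nerve = nerve, fascicles = fascicles, scale = scale,
                      shrinkage_applied = shrinkage_applied,
                      min_separation = min_separation),
                 class = "nerve_sample")
  if (validate) validate_sample(s)
  s
}

#' @param inners a `trace` or list of `trace`s (inner perineurium)
#' @param outer optional outer perineurium `trace`
#' @rdname nerve_sample
#' @export
fascicle <- function(inners, outer = NULL) {
  if (is_trace(inners)) inners <- list(inners)
  stopifnot(length(inners) >= 1L, all(vapply(inners, is_trace, TRUE)))
  if (!is.null(outer)) stopifnot(is_trace(outer))
  structure(list(inners = inners, outer = outer), class = "fascicle")
}

# the trace used for containment/separation checks: outer if present, else
# the single inner
fascicle_boundary <- function(f) {
  if (!is.null(f$outer)) f$outer else f$inners[[1L]]
}

#' @exportS3Method base::print
print.nerve_sample <- function(x, ...) {
  cat(sprintf("<nerve_sample> %d fascicle(s)%s\n", length(x$fascicles),
              if (is.null(x$nerve)) ", no nerve trace" else
                sprintf(", nerve area %.0f um^2", trace_area(x$nerve))))
  invisible(x)
}

#' Validate a nerve sample's geometric invariants
#'
#' Checks that every fascicle lies strictly inside the nerve trace (when
#' present), fascicles are pairwise disjoint with boundary separation at
#' least `x$min_separation`, and each fascicle's inners lie inside its outer.
#'
#' @param x a `nerve_sample`
#' @return invisibly `TRUE`; stops with a message listing offenders otherwise
#' @export
validate_sample <- function(x) {
  offenders <- character()
  nf <- length(x$fascicles)
  bounds <- lapply(x$fascicles, fascicle_boundary)
  if (!is.null(x$nerve)) {
    for (i in seq_len(nf))
      if (!trace_inside(bounds[[i]], x$nerve, margin = 0))
        offenders <- c(offenders, sprintf("fascicle %d not inside nerve", i))
  }
  if (nf >= 2L) {
    for (i in seq_len(nf - 1L)) for (j in (i + 1L):nf) {
      if (traces_overlap(bounds[[i]], bounds[[j]]) ||
          trace_boundary_distance(bounds[[i]], bounds[[j]]) < x$min_separation)
        offenders <- c(offenders,
                       sprintf("fascicles %d and %d overlap or are closer than %g um",
                               i, j, x$min_separation))
    }
  }
  for (i in seq_len(nf)) {
    f <- x$fascicles[[i]]
    if (!is.null(f$outer)) {
      for (k in seq_along(f$inners))
        if (!trace_inside(f$inners[[k]], f$outer))
          offenders <- c(offenders,
                         sprintf("fascicle %d inner %d not inside its outer", i, k))
    }
    if (length(f$inners) >= 2L) {
      for (a in seq_len(length(f$inners) - 1L))
        for (b in (a + 1L):length(f$inners))
          if (traces_overlap(f$inners[[a]], f$inners[[b]]))
            offenders <- c(offenders, sprintf("fascicle %d inners overlap", i))
    }
  }
  if (length(offenders))
    stop("invalid nerve sample:\n  ", paste(offenders, collapse = "\n  "))
  invisible(TRUE)
}

#' Mock morphology parameters
#'
#' Parameter container for the mock (synthetic) nerve morphology generator,
#' in either of two modes. `explicit` mode places user-specified elliptical
#' fascicles; `probabilistic` mode draws fascicle diameters, eccentricities
#' and rotations from distributions and places them by disk point picking
#' with rejection.
#'
#' @param mode `"explicit"` or `"probabilistic"`
#' @param nerve list(a, b, center, rotation): nerve ellipse semi-axes (um),
#'   centroid and rotation (deg)
#' @param fascicles explicit mode: list of list(a, b, center, rotation)
#' @param count probabilistic mode: number of fascicles to attempt
#' @param diameter list(mean, sd, min, max): truncated-normal effective
#'   diameter distribution (um)
#' @param eccentricity list(min, max): uniform eccentricity range in [0, 1)
#' @param rotation_range length-2 degrees (uniform)
#' @param min_separation minimum boundary separation (um) between fascicles
#'   and from the nerve boundary
#' @param max_attempts placement attempts per fascicle before skipping
#' @param seed RNG seed (probabilistic mode)
#' @param n_vertices polygon vertices per ellipse
#' @return an object of class `mock_params`
#' @export
mock_params <- function(mode = c("probabilistic", "explicit"),
                        nerve = list(a = 500, b = 400, center = c(0, 0),
                                     rotation = 0),
                        fascicles = NULL,
                        count = 5L,
                        diameter = list(mean = 200, sd = 40, min = 80,
                                        max = 400),
                        eccentricity = list(min = 0, max = 0.6),
                        rotation_range = c(0, 180),
                        min_separation = 10,
                        max_attempts = 100L,
                        seed = 1L,
                        n_vertices = 100L) {
  mode <- match.arg(mode)
  stopifnot(min_separation >= 0, n_vertices >= 8L)
  if (mode == "probabilistic") {
    stopifnot(count >= 1L, diameter$sd >= 0, diameter$min <= diameter$max,
              eccentricity$min <= eccentricity$max, eccentricity$min >= 0,
              eccentricity$max < 1, max_attempts >= 1L)
  } else if (is.null(fascicles) || !length(fascicles)) {
    stop("explicit mode requires a list of fascicle ellipses")
  }
  structure(list(mode = mode, nerve = nerve, fascicles = fascicles,
                 count = as.integer(count), diameter = diameter,
                 eccentricity = eccentricity,
                 rotation_range = rotation_range,
                 min_separation = min_separation,
                 max_attempts = as.integer(max_attempts),
                 seed = as.integer(seed),
                 n_vertices = as.integer(n_vertices)),
            class = "mock_params")
}

#' Generate mock morphology with explicit fascicle ellipses
#'
#' Builds a nerve sample from a nerve ellipse and a user-specified list of
#' fascicle ellipses. Deterministic: the same parameters always produce
#' identical vertex lists.
#'
#' @param params a [mock_params()] with `mode = "explicit"`
#' @return a validated `nerve_sample`
#' @export
generate_mock_explicit <- function(params) {
  stopifnot(inherits(params, "mock_params"), params$mode == "explicit")
  nerve <- with(params$nerve,
                ellipse_trace(a, b, center, rotation, params$n_vertices))
  fas <- lapply(params$fascicles, function(e) {
    rot <- if (is.null(e$rotation)) 0 else e$rotation
    ctr <- if (is.null(e$center)) c(0, 0) else e$center
    fascicle(ellipse_trace(e$a, e$b, ctr, rot, params$n_vertices))
  })
  nerve_sample(nerve, fas, min_separation = params$min_separation)
}

#' Generate mock morphology probabilistically
#'
#' Draws fascicle effective diameters from a truncated normal,
#' eccentricities and rotations from uniform distributions, and places
#' fascicle centroids by uniform disk point picking inside the nerve
#' ellipse. A candidate placement is accepted only when the fascicle
#' boundary keeps at least `min_separation` um from the nerve boundary and
#' every previously placed fascicle; after `max_attempts` failed placements
#' the fascicle is skipped with a warning. A fixed seed makes the result
#' fully reproducible.
#'
#' @param params a [mock_params()] with `mode = "probabilistic"`
#' @return a validated `nerve_sample` with attribute `"skipped"` giving the
#'   number of fascicles that could not be placed
#' @export
generate_mock_probabilistic <- function(params) {
  stopifnot(inherits(params, "mock_params"), params$mode == "probabilistic")
  rng <- local_rng(params$seed)
  nerve <- with(params$nerve,
                ellipse_trace(a, b, center, rotation, params$n_vertices))
  nctr <- trace_centroid(nerve)
  rmax <- max(params$nerve$a, params$nerve$b)
  placed <- list()
  skipped <- 0L
  for (i in seq_len(params$count)) {
    d <- rtruncnorm1(rng, params$diameter$mean, params$diameter$sd,
                     params$diameter$min, params$diameter$max)
    ecc <- runif_rng(rng, params$eccentricity$min, params$eccentricity$max)
    rot <- runif_rng(rng, params$rotation_range[1], params$rotation_range[2])
    # semi-axes from effective diameter and eccentricity: b = a*sqrt(1-e^2),
    # a*b = (d/2)^2
    b_over_a <- sqrt(1 - ecc^2)
    a <- (d / 2) / sqrt(b_over_a)
    b <- a * b_over_a
    ok <- FALSE
    for (att in seq_len(params$max_attempts)) {
      # disk point picking: uniform over the nerve ellipse
      u <- runif_rng(rng, 0, 1)
      th <- runif_rng(rng, 0, 2 * pi)
      r <- sqrt(u)
      ctr0 <- c(params$nerve$a * r * cos(th), params$nerve$b * r * sin(th))
      rr <- params$nerve$rotation * pi / 180
      ctr <- nctr + c(cos(rr) * ctr0[1] - sin(rr) * ctr0[2],
                      sin(rr) * ctr0[1] + cos(rr) * ctr0[2])
      cand <- ellipse_trace(a, b, ctr, rot, params$n_vertices)
      if (!trace_inside(cand, nerve, margin = params$min_separation)) next
      sep_ok <- TRUE
      for (p in placed) {
        bd <- fascicle_boundary(p)
        if (traces_overlap(cand, bd) ||
            trace_boundary_distance(cand, bd) < params$min_separation) {
          sep_ok <- FALSE
          break
        }
      }
      if (sep_ok) {
        placed[[length(placed) + 1L]] <- fascicle(cand)
        ok <- TRUE
        break
      }
    }
    if (!ok) skipped <- skipped + 1L
  }
  if (!length(placed))
    stop("no fascicles could be placed; relax min_separation or sizes")
  if (skipped > 0L)
    warning(sprintf("skipped %d of %d fascicles after %d attempts each",
                    skipped, params$count, params$max_attempts))
  s <- nerve_sample(nerve, placed, min_separation = params$min_separation)
  attr(s, "skipped") <- skipped
  s
}

#' Correct for histological tissue shrinkage
#'
#' Scales all traces about the nerve centroid so linear dimensions are
#' multiplied by 1/(1 - shrinkage); areas scale by the square. Relative
#' fascicle positions are preserved (similarity transform).
#'
#' @param sample a `nerve_sample`
#' @param shrinkage shrinkage fraction in [0, 1)
#' @return the corrected `nerve_sample` with `shrinkage_applied` recorded
#' @export
apply_shrinkage_correction <- function(sample, shrinkage) {
  if (shrinkage < 0 || shrinkage >= 1)
    stop("shrinkage must be in [0, 1)")
  f <- 1 / (1 - shrinkage)
  about <- if (!is.null(sample$nerve)) trace_centroid(sample$nerve)
           else trace_centroid(fascicle_boundary(sample$fascicles[[1L]]))
  scale_tr <- function(tr) trace_scale(tr, f, about)
  if (!is.null(sample$nerve)) sample$nerve <- scale_tr(sample$nerve)
  sample$fascicles <- lapply(sample$fascicles, function(fa) {
    fa$inners <- lapply(fa$inners, scale_tr)
    if (!is.null(fa$outer)) fa$outer <- scale_tr(fa$outer)
    fa
  })
  sample$min_separation <- sample$min_separation * f
  sample$shrinkage_applied <- shrinkage
  sample
}

#' Deform a nerve to conform to a circular cuff aperture
#'
#' Maps the nerve boundary onto a circle of the cuff's inner diameter by
#' per-vertex radial scaling about the nerve centroid. Each fascicle is
#' translated rigidly by the radial displacement interpolated at its
#' centroid (fascicle areas are untouched), then residual overlaps and
#' boundary escapes are resolved by iterative pairwise repulsion along
#' centroid-centroid axes.
#'
#' @param sample a `nerve_sample` with a nerve trace
#' @param cuff_inner_diameter target circle diameter (um)
#' @param max_iter repulsion iteration cap (default 200)
#' @return the deformed `nerve_sample`
#' @export
deform_to_cuff <- function(sample, cuff_inner_diameter, max_iter = 200L) {
  stopifnot(!is.null(sample$nerve), cuff_inner_diameter > 0)
  R <- cuff_inner_diameter / 2
  ctr <- trace_centroid(sample$nerve)
  min_sep <- sample$min_separation
  fas_area <- sum(vapply(sample$fascicles,
                         function(f) trace_area(fascicle_boundary(f)), 0))
  if (fas_area > 0.9 * pi * R^2)
    stop("total fascicle area exceeds achievable packing in the target circle")

  # boundary radius as a function of angle (piecewise from vertices)
  pts <- sample$nerve$points
  ang <- atan2(pts[, 2] - ctr[2], pts[, 1] - ctr[1])
  rad <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
  o <- order(ang)
  ang <- ang[o]; rad <- rad[o]
  boundary_radius <- function(theta) {
    # periodic linear interpolation
    a <- c(ang - 2 * pi, ang, ang + 2 * pi)
    r <- c(rad, rad, rad)
    stats::approx(a, r, xout = theta, rule = 2)$y
  }

  move <- function(tr) {
    c0 <- trace_centroid(tr)
    v <- c0 - ctr
    r0 <- sqrt(sum(v^2))
    if (r0 < 1e-9) return(tr)
    th <- atan2(v[2], v[1])
    s <- R / boundary_radius(th)
    trace_translate(tr, v * (s - 1))
  }
  sample$fascicles <- lapply(sample$fascicles, function(fa) {
    d <- trace_centroid(fascicle_boundary(fa))
    fa2 <- fa
    fa2$inners <- lapply(fa$inners, function(tr) {
      # rigid translation by the displacement at the fascicle centroid
      moved_ctr <- trace_centroid(move(fascicle_boundary(fa)))
      trace_translate(tr, moved_ctr - d)
    })
    if (!is.null(fa$outer)) {
      moved_ctr <- trace_centroid(move(fascicle_boundary(fa)))
      fa2$outer <- trace_translate(fa$outer, moved_ctr - d)
    }
    fa2
  })

  # iterative repulsion to restore disjointness and containment
  nf <- length(sample$fascicles)
  for (iter in seq_len(max_iter)) {
    bounds <- lapply(sample$fascicles, fascicle_boundary)
    shifts <- matrix(0, nf, 2)
    dirty <- FALSE
    # containment in the target circle
    for (i in seq_len(nf)) {
      p <- bounds[[i]]$points
      rr <- sqrt((p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2)
      excess <- max(rr) - (R - min_sep)
      if (excess > 0) {
        k <- which.max(rr)
        u <- (p[k, ] - ctr) / rr[k]
        shifts[i, ] <- shifts[i, ] - u * (excess + 0.5)
        dirty <- TRUE
      }
    }
    # pairwise separation
    if (nf >= 2L) for (i in seq_len(nf - 1L)) for (j in (i + 1L):nf) {
      overlap <- traces_overlap(bounds[[i]], bounds[[j]])
      gap <- trace_boundary_distance(bounds[[i]], bounds[[j]])
      if (overlap || gap < min_sep) {
        ci <- trace_centroid(bounds[[i]])
        cj <- trace_centroid(bounds[[j]])
        u <- cj - ci
        nu <- sqrt(sum(u^2))
        u <- if (nu < 1e-9) c(1, 0) else u / nu
        depth <- if (overlap) overlap_depth(bounds[[i]], bounds[[j]]) else 0
        step <- (depth + (min_sep - min(gap, min_sep)) + 0.5) / 2
        shifts[i, ] <- shifts[i, ] - u * step
        shifts[j, ] <- shifts[j, ] + u * step
        dirty <- TRUE
      }
    }
    if (!dirty) break
    for (i in seq_len(nf)) {
      if (any(shifts[i, ] != 0)) {
        fa <- sample$fascicles[[i]]
        fa$inners <- lapply(fa$inners, trace_translate, dxy = shifts[i, ])
        if (!is.null(fa$outer))
          fa$outer <- trace_translate(fa$outer, shifts[i, ])
        sample$fascicles[[i]] <- fa
      }
    }
    if (iter == max_iter)
      stop("deform_to_cuff: repulsion did not converge; fascicles may not fit")
  }

  sample$nerve <- ellipse_trace(R, R, ctr, 0,
                                n_vertices = nrow(sample$nerve$points))
  validate_sample(sample)
  sample
}

# crude overlap depth estimate: how far vertices of one polygon intrude into
# the other
overlap_depth <- function(t1, t2) {
  d <- 0
  in2 <- points_in_trace(t1$points, t2)
  if (any(in2))
    d <- max(d, max(points_to_polygon_distance(t1$points[in2, , drop = FALSE],
                                               t2$points)))
  in1 <- points_in_trace(t2$points, t1)
  if (any(in1))
    d <- max(d, max(points_to_polygon_distance(t2$points[in1, , drop = FALSE],
                                               t1$points)))
  d
}

# ---- seeded RNG helpers -----------------------------------------------------
# a private RNG stream so generation is a pure function of (params, seed)
# and never disturbs the caller's .Random.seed
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())
  env
}

with_rng <- function(rng, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", rng$state, globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  })
  expr
}

runif_rng <- function(rng, min = 0, max = 1)
  with_rng(rng, stats::runif(1, min, max))

rnorm_rng <- function(rng, mean = 0, sd = 1)
  with_rng(rng, stats::rnorm(1, mean, sd))

# one truncated-normal draw by rejection
rtruncnorm1 <- function(rng, mean, sd, lo, hi) {
  if (sd == 0) return(min(max(mean, lo), hi))
  for (i in 1:10000) {
    x <- rnorm_rng(rng, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  stop("truncated-normal rejection failed; check bounds")
}
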