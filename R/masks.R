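#' Build a nerve sample from segmented binary masks
#'
#' Reads single-channel binary masks following the n/i/o/s naming
#' convention: `n` = nerve boundary, `i` = fascicle inners, `o` = fascicle
#' outers (optional), `s` = a horizontal scale bar of known physical
#' length. Foreground is any nonzero pixel. Contours of connected
#' components become traces in um, with the image origin mapped so the
#' nerve centroid sits at (0, 0). Inners are matched to their containing
#' outers; several inners under one outer form a "peanut" fascicle.
#'
#' Mask reading requires the `tiff`/`png` and `EBImage` packages.
#'
#' @param mask_paths named list/character vector with elements `n`, `i`,
#'   optionally `o`, and `s` (paths to TIFF or PNG files)
#' @param scale_bar_length physical length of the scale bar (um)
#' @return a validated `nerve_sample` with `scale` = um per pixel
#' @export
load_sample_masks <- function(mask_paths, scale_bar_length) {
  mask_paths <- as.list(mask_paths)
  req <- c("n", "i", "s")
  if (!all(req %in% names(mask_paths)))
    stop("mask_paths must name at least 'n', 'i' and 's' masks")
  stopifnot(scale_bar_length > 0)
  masks <- lapply(mask_paths, read_mask)
  dims <- lapply(masks, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("mask images must share dimensions")
  for (nm in names(masks)) if (!any(masks[[nm]]))
    stop(sprintf("mask '%s' is empty", nm))

  # scale: longest horizontal run of foreground pixels in the scale bar
  run <- max_horizontal_run(masks$s)
  if (run < 2L) stop("scale bar mask contains no horizontal run")
  um_per_px <- scale_bar_length / run

  nerve_tr <- mask_contours(masks$n, um_per_px)
  if (length(nerve_tr) != 1L)
    stop("nerve mask must contain exactly one connected component")
  nerve_tr <- nerve_tr[[1L]]
  inner_tr <- mask_contours(masks$i, um_per_px)
  outer_tr <- if (!is.null(masks$o)) mask_contours(masks$o, um_per_px)
              else list()

  # center on the nerve centroid
  ctr <- trace_centroid(nerve_tr)
  recenter <- function(tr) trace_translate(tr, -ctr)
  nerve_tr <- recenter(nerve_tr)
  inner_tr <- lapply(inner_tr, recenter)
  outer_tr <- lapply(outer_tr, recenter)

  if (length(outer_tr)) {
    assigned <- integer(length(inner_tr))
    for (k in seq_along(inner_tr)) {
      hit <- which(vapply(outer_tr, function(o)
        all(points_in_trace(inner_tr[[k]]$points, o)), TRUE))
      if (!length(hit))
        stop(sprintf("inner %d has no containing outer", k))
      assigned[k] <- hit[1L]
    }
    fas <- lapply(seq_along(outer_tr), function(j) {
      inn <- inner_tr[assigned == j]
      if (!length(inn)) return(NULL)
      fascicle(inn, outer = outer_tr[[j]])
    })
    fas <- Filter(Negate(is.null), fas)
  } else {
    fas <- lapply(inner_tr, fascicle)
  }
  nerve_sample(nerve_tr, fas, scale = um_per_px)
}

read_mask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = {
      requireNamespace("tiff", quietly = TRUE) ||
        stop("package 'tiff' is required to read TIFF masks")
      tiff::readTIFF(path)
    },
    png = {
      requireNamespace("png", quietly = TRUE) ||
        stop("package 'png' is required to read PNG masks")
      png::readPNG(path)
    },
    stop("unsupported mask format: ", ext))
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img > 0
}

max_horizontal_run <- function(mask) {
  best <- 0L
  for (r in seq_len(nrow(mask))) {
    v <- rle(mask[r, ])
    runs <- v$lengths[v$values]
    if (length(runs)) best <- max(best, max(runs))
  }
  best
}

# contours of connected foreground components, converted to traces in um.
# readTIFF/readPNG give row-major images with row 1 at the top; flip y so
# the y axis points up.
mask_contours <- function(mask, um_per_px) {
  requireNamespace("EBImage", quietly = TRUE) ||
    stop("package 'EBImage' is required for mask contour extraction")
  # EBImage images are indexed [x, y]; transpose the row-major matrix
  lab <- EBImage::bwlabel(EBImage::Image(t(mask * 1)))
  ocs <- EBImage::ocontour(lab)
  nr <- nrow(mask)
  lapply(ocs, function(oc) {
    # oc columns: x (image col), y (image row); flip to y-up, scale to um
    pts <- cbind(oc[, 1], nr - oc[, 2])
    pts <- pts[!duplicated(pts), , drop = FALSE]
    tr <- nerve_trace(pts, validate = FALSE)
    # the contour passes through boundary-pixel centers; the region extends
    # half a pixel beyond it. Offsetting outward by d = 1/2 px grows the
    # area by P*d + pi*d^2 (convex offset formula); apply it as a uniform
    # scale about the centroid.
    A <- trace_area(tr)
    P <- polygon_perimeter(tr$points)
    s <- sqrt((A + P * 0.5 + pi * 0.25) / A)
    tr <- trace_scale(tr, s, about = trace_centroid(tr))
    tr$points <- tr$points * um_per_px
    simplify_trace(tr)
  })
}

polygon_perimeter <- function(pts) {
  n <- nrow(pts)
  j <- c(2:n, 1L)
  sum(sqrt((pts[j, 1] - pts[, 1])^2 + (pts[j, 2] - pts[, 2])^2))
}

# drop collinear runs so pixel-staircase contours stay manageable
simplify_trace <- function(tr, tol = 1e-9) {
  p <- tr$points
  n <- nrow(p)
  if (n <= 16L) return(tr)
  keep <- rep(TRUE, n)
  prev <- p[c(n, 1:(n - 1L)), , drop = FALSE]
  nxt <- p[c(2:n, 1L), , drop = FALSE]
  cr <- (p[, 1] - prev[, 1]) * (nxt[, 2] - p[, 2]) -
        (p[, 2] - prev[, 2]) * (nxt[, 1] - p[, 1])
  keep[abs(cr) <= tol] <- FALSE
  if (sum(keep) >= 3L) tr$points <- p[keep, , drop = FALSE]
  tr
}

#' Serialize / deserialize nerve sample geometry as JSON
#'
#' Writes traces as polygon vertex lists in um, together with scale and
#' shrinkage provenance, and reads them back.
#'
#' @param sample a `nerve_sample`
#' @param path output (input) file path
#' @return `write_sample_json` the path invisibly; `read_sample_json` a
#'   `nerve_sample`
#' @export
write_sample_json <- function(sample, path) {
  obj <- list(
    scale = sample$scale,
    shrinkage_applied = sample$shrinkage_applied,
    min_separation = sample$min_separation,
    nerve = if (!is.null(sample$nerve)) sample$nerve$points,
    fascicles = lapply(sample$fascicles, function(f) list(
      inners = lapply(f$inners, function(tr) tr$points),
      outer = if (!is.null(f$outer)) f$outer$points))
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_sample_json
#' @export
read_sample_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  as_tr <- function(m) {
    if (is.null(m)) return(NULL)
    pts <- do.call(rbind, lapply(m, function(row) unlist(row)))
    nerve_trace(pts, validate = FALSE)
  }
  fascicles <- lapply(obj$fascicles, function(el)
    fascicle(lapply(el$inners, as_tr), outer = as_tr(el$outer)))
  nerve_sample(as_tr(obj$nerve), fascicles,
               scale = if (is.null(obj$scale)) NA_real_ else obj$scale,
               shrinkage_applied = obj$shrinkage_applied %||% 0,
               min_separation = obj$min_separation %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
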