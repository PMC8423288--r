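#' Parameterized cuff electrode
#'
#' A cuff is an insulating cylinder of a given inner diameter and length
#' carrying one or more metal contacts on its inner surface. Each contact
#' is described by its angular center and span, axial center and span, and
#' an optional radial recess. For field computation each contact is reduced
#' to a point current source at its center; spans are retained for plotting
#' and future distributed-source extensions.
#'
#' @param inner_diameter cuff aperture diameter (um)
#' @param length cuff length along z (um)
#' @param contacts list of contacts, each
#'   `list(theta_center, theta_span, z_center, z_span, recess)` with angles
#'   in degrees (CCW from +x) and lengths in um
#' @param fill_material name of the material filling the aperture
#' @param insulated logical; is the outer cuff surface insulating
#' @param name preset or user label
#' @return an object of class `cuff_spec`
#' @examples
#' cuff_spec(300, 2000, list(list(theta_center = 0, theta_span = 120,
#'                                z_center = 0, z_span = 500, recess = 0)))
#' @export
cuff_spec <- function(inner_diameter, length, contacts,
                      fill_material = "saline", insulated = TRUE,
                      name = "custom") {
  stopifnot(inner_diameter > 0, length > 0, length(contacts) >= 1L)
  contacts <- lapply(contacts, function(ct) {
    ct$recess <- ct$recess %||% 0
    ct$theta_span <- ct$theta_span %||% 0
    ct$z_span <- ct$z_span %||% 0
    stopifnot(ct$z_span >= 0, ct$theta_span >= 0, ct$recess >= 0)
    if (abs(ct$z_center) + ct$z_span / 2 > length / 2)
      stop("contact extends beyond the cuff length")
    ct
  })
  structure(list(inner_diameter = inner_diameter, length = length,
                 contacts = contacts, fill_material = fill_material,
                 insulated = insulated, name = name),
            class = "cuff_spec")
}

#' Preset cuff geometries
#'
#' Generic ring-cuff presets: `"monopolar_ring"` (one contact) and
#' `"bipolar_ring"` (two contacts at +/- `pitch/2` along z). Dimensions are
#' user-supplied; no commercial geometry is reproduced.
#'
#' @param preset preset name
#' @param inner_diameter,length cuff dimensions (um)
#' @param theta_span contact angular span (deg)
#' @param z_span contact axial span (um)
#' @param pitch bipolar contact center-to-center distance (um)
#' @return a `cuff_spec`
#' @export
cuff_preset <- function(preset = c("monopolar_ring", "bipolar_ring"),
                        inner_diameter = 300, length = 4000,
                        theta_span = 270, z_span = 400, pitch = 2000) {
  preset <- match.arg(preset)
  contacts <- switch(preset,
    monopolar_ring = list(list(theta_center = 0, theta_span = theta_span,
                               z_center = 0, z_span = z_span, recess = 0)),
    bipolar_ring = list(
      list(theta_center = 0, theta_span = theta_span,
           z_center = -pitch / 2, z_span = z_span, recess = 0),
      list(theta_center = 0, theta_span = theta_span,
           z_center = pitch / 2, z_span = z_span, recess = 0)))
  cuff_spec(inner_diameter, length, contacts, name = preset)
}

#' Place a cuff on a nerve sample
#'
#' Positions the cuff around the nerve with an additional rotation
#' `add_ang` and axial center `z_center`. Every contact yields one point
#' current source at angle `theta_center + add_ang`, radius
#' `inner_diameter/2 - recess`, and height `z_center(contact) +
#' z_center(cuff)`.
#'
#' @param spec a `cuff_spec`
#' @param sample a `nerve_sample` (deform with [deform_to_cuff()] first);
#'   `NULL` skips the aperture-fit check
#' @param add_ang cuff rotation (deg, CCW)
#' @param z_center cuff axial center (um)
#' @return an object of class `cuff_placement` with a `source_points`
#'   matrix (one row per contact: x, y, z in um)
#' @export
place_cuff <- function(spec, sample = NULL, add_ang = 0, z_center = 0) {
  stopifnot(inherits(spec, "cuff_spec"))
  if (!is.null(sample) && !is.null(sample$nerve)) {
    ctr <- trace_centroid(sample$nerve)
    r <- sqrt((sample$nerve$points[, 1] - ctr[1])^2 +
              (sample$nerve$points[, 2] - ctr[2])^2)
    if (max(r) > spec$inner_diameter / 2 + 1e-6)
      stop("nerve boundary exceeds the cuff aperture; run deform_to_cuff first")
  }
  sp <- t(vapply(spec$contacts, function(ct) {
    th <- (ct$theta_center + add_ang) * pi / 180
    r <- spec$inner_diameter / 2 - ct$recess
    c(r * cos(th), r * sin(th), ct$z_center + z_center)
  }, numeric(3)))
  colnames(sp) <- c("x", "y", "z")
  structure(list(cuff = spec, add_ang = add_ang, z_center = z_center,
                 xy_offset = c(0, 0), source_points = sp),
            class = "cuff_placement")
}

#' @exportS3Method base::print
print.cuff_placement <- function(x, ...) {
  cat(sprintf("<cuff_placement> %s, %d contact(s), add_ang %g deg\n",
              x$cuff$name, nrow(x$source_points), x$add_ang))
  invisible(x)
}

#' Read / write a cuff specification as JSON
#' @param path file path
#' @param spec a `cuff_spec`
#' @return `read_cuff_json` a `cuff_spec`
#' @export
read_cuff_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = FALSE)
  cuff_spec(o$inner_diameter, o$length, o$contacts,
            fill_material = o$fill_material %||% "saline",
            insulated = o$insulated %||% TRUE, name = o$name %||% "custom")
}

#' @rdname read_cuff_json
#' @export
write_cuff_json <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
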