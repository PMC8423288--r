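#' Material conductivities
#'
#' Materials carry a diagonal conductivity tensor (sigma_x, sigma_y,
#' sigma_z) in S/m. The built-in library covers the tissues and media of a
#' peripheral-nerve stimulation model: anisotropic endoneurium (higher
#' longitudinal conductivity), highly resistive perineurium, epineurium,
#' encapsulation tissue, a muscle surrounding medium, saline cuff fill, and
#' an effectively insulating cuff material.
#'
#' @param name material name
#' @param sigma length-1 (isotropic) or length-3 conductivity (S/m)
#' @return an object of class `material`
#' @examples
#' get_material("endoneurium")$sigma
#' @export
material <- function(name, sigma) {
  if (length(sigma) == 1L) sigma <- rep(sigma, 3)
  stopifnot(length(sigma) == 3L, all(sigma > 0))
  structure(list(name = name, sigma = as.numeric(sigma)), class = "material")
}

.material_library <- list(
  endoneurium   = c(0.167, 0.167, 0.571),
  perineurium   = c(0.0008703, 0.0008703, 0.0008703),
  epineurium    = c(0.159, 0.159, 0.159),
  encapsulation = c(0.159, 0.159, 0.159),
  muscle_medium = c(0.086, 0.086, 0.35),
  saline        = c(1.76, 1.76, 1.76),
  cuff_insulator = c(1e-7, 1e-7, 1e-7)
)

#' @rdname material
#' @param custom optional named list of user-defined tensors overriding or
#'   extending the built-ins (e.g. parsed from a model JSON)
#' @export
get_material <- function(name, custom = NULL) {
  if (!is.null(custom) && name %in% names(custom))
    return(material(name, unlist(custom[[name]])))
  if (!name %in% names(.material_library))
    stop("unknown material: ", name)
  material(name, .material_library[[name]])
}

#' @exportS3Method base::print
print.material <- function(x, ...) {
  cat(sprintf("<material> %s: sigma = {%g, %g, %g} S/m\n", x$name,
              x$sigma[1], x$sigma[2], x$sigma[3]))
  invisible(x)
}

#' Perineurium thin-layer sheet resistivity
#'
#' The perineurium is thin and highly resistive; rather than resolving it
#' on the solver grid it can be represented as a sheet resistance
#' rho_s = thickness / sigma (Ohm m^2) on the fascicle boundary. The
#' default thickness is 3 percent of the inner trace's effective diameter;
#' pass `thickness_um` to override. This default is a modeling choice and
#' is always reported in the returned object.
#'
#' @param inner the fascicle inner `trace`
#' @param thickness_um explicit perineurium thickness (um); default
#'   `0.03 * effective diameter`
#' @param sigma perineurium conductivity (S/m)
#' @return list(thickness_um, rho_s) with rho_s in Ohm m^2
#' @export
perineurium_layer <- function(inner, thickness_um = NULL,
                              sigma = get_material("perineurium")$sigma[1]) {
  if (is.null(thickness_um))
    thickness_um <- 0.03 * trace_effective_diameter(inner)
  stopifnot(thickness_um >= 0, sigma > 0)
  list(thickness_um = thickness_um, rho_s = (thickness_um * 1e-6) / sigma)
}
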