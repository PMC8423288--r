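#' Analytic point-source basis field
#'
#' Closed-form potential of a point current source in an unbounded
#' homogeneous medium with a diagonal anisotropic conductivity tensor:
#' \deqn{\phi(\Delta) = \frac{I}{4\pi\sqrt{\sigma_x\sigma_y\sigma_z}
#'   \sqrt{\Delta_x^2/\sigma_x + \Delta_y^2/\sigma_y +
#'         \Delta_z^2/\sigma_z}}}
#' which reduces to \eqn{I/(4\pi\sigma r)} for isotropic media. The basis
#' carries unit current I = 1 mA; arbitrary contact currents follow by
#' weighted superposition.
#'
#' @param placement a `cuff_placement`
#' @param contact contact index (1-based)
#' @param sigma a `material` (the homogeneous medium)
#' @return an object of class `basis_field` (solver `"analytic"`)
#' @export
solve_basis_analytic <- function(placement, contact,
                                 sigma = get_material("endoneurium")) {
  stopifnot(inherits(placement, "cuff_placement"),
            contact >= 1L, contact <= nrow(placement$source_points),
            inherits(sigma, "material"))
  structure(list(solver = "analytic",
                 contact_index = as.integer(contact),
                 source = placement$source_points[contact, ],
                 sigma = sigma$sigma,
                 current_mA = 1),
            class = "basis_field")
}

#' @exportS3Method base::print
print.basis_field <- function(x, ...) {
  cat(sprintf("<basis_field> analytic, contact %d, source (%.0f, %.0f, %.0f) um\n",
              x$contact_index, x$source[1], x$source[2], x$source[3]))
  invisible(x)
}

# evaluate an analytic basis at coords (n x 3, um) -> V
eval_analytic <- function(bf, coords) {
  coords <- rbind(coords)
  d <- t(t(coords) - bf$source) * 1e-6  # um -> m
  s <- bf$sigma
  q <- sqrt(d[, 1]^2 / s[1] + d[, 2]^2 / s[2] + d[, 3]^2 / s[3])
  if (any(q == 0))
    stop("potential is singular at the source point")
  (bf$current_mA * 1e-3) / (4 * pi * sqrt(prod(s)) * q)
}

#' Regular solver grid specification
#'
#' Cells are cubic by default; a length-3 `spacing` gives a rectilinear
#' grid. For strongly anisotropic media, choosing per-axis spacings
#' proportional to the square roots of the conductivity components makes
#' cells cubic in the conductivity-stretched coordinates in which the
#' governing equation becomes an isotropic Laplacian, which equalizes the
#' discretization error across directions.
#'
#' @param origin length-3 (x, y, z) of the first grid node (um)
#' @param spacing cell edge (um); scalar or length-3
#' @param shape length-3 integer node counts (nx, ny, nz)
#' @return an object of class `grid_spec`
#' @export
grid_spec <- function(origin, spacing, shape) {
  shape <- as.integer(shape)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  stopifnot(length(origin) == 3L, length(spacing) == 3L, all(spacing > 0),
            length(shape) == 3L, all(shape >= 3L))
  structure(list(origin = as.numeric(origin), spacing = as.numeric(spacing),
                 shape = shape), class = "grid_spec")
}

grid_axes <- function(g)
  lapply(1:3, function(k) g$origin[k] + g$spacing[k] * (seq_len(g$shape[k]) - 1L))

#' Conductivity map for the finite-difference solver
#'
#' The solver domain is filled with `background`; each entry of `regions`
#' paints a polygonal prism (a cross-sectional trace extruded over a
#' z-extent) with another material, in order. `thin_layers` registers
#' fascicle boundaries that carry a perineurium sheet resistance rho_s
#' (Ohm m^2): grid faces crossing a registered boundary get the extra
#' series resistance instead of a meshed layer.
#'
#' @param background a `material`
#' @param regions list of `list(trace =, z_extent = c(z0, z1), material =)`
#' @param thin_layers list of `list(trace =, z_extent =, rho_s =)`
#' @return an object of class `conductivity_map`
#' @export
conductivity_map <- function(background, regions = list(),
                             thin_layers = list()) {
  stopifnot(inherits(background, "material"))
  for (r in regions)
    stopifnot(is_trace(r$trace), length(r$z_extent) == 2L,
              inherits(r$material, "material"))
  for (tl in thin_layers)
    stopifnot(is_trace(tl$trace), tl$rho_s >= 0)
  structure(list(background = background, regions = regions,
                 thin_layers = thin_layers), class = "conductivity_map")
}

# node conductivity arrays (nx x ny x nz) for one tensor component
build_sigma_arrays <- function(cmap, grid) {
  ax <- grid_axes(grid)
  nx <- grid$shape[1]; ny <- grid$shape[2]; nz <- grid$shape[3]
  sig <- lapply(1:3, function(k) array(cmap$background$sigma[k],
                                       dim = grid$shape))
  if (length(cmap$regions)) {
    xy <- cbind(rep(ax[[1]], times = ny), rep(ax[[2]], each = nx))
    for (r in cmap$regions) {
      inside2d <- points_in_trace(xy, r$trace)  # length nx*ny
      kz <- which(ax[[3]] >= min(r$z_extent) & ax[[3]] <= max(r$z_extent))
      if (!any(inside2d) || !length(kz)) next
      idx2 <- which(inside2d)
      for (k in 1:3) {
        m <- sig[[k]]
        for (z in kz) m[idx2 + (z - 1L) * nx * ny] <- r$material$sigma[k]
        sig[[k]] <- m
      }
    }
  }
  sig
}

#' Solve one contact's basis potentials on a finite-difference grid
#'
#' Seven-point finite-difference discretization of the quasi-static
#' volume-conductor equation div(sigma grad phi) = 0 with a unit (1 mA)
#' point current injected at the grid node nearest the contact's source
#' point. Face conductances are harmonic means of the adjacent node
#' conductivities; faces crossing a registered fascicle boundary carry the
#' perineurium sheet resistance in series. The symmetric positive-definite
#' system is solved by Jacobi-preconditioned conjugate gradients to a
#' relative residual of `tol`.
#'
#' Boundary conditions: `"grounded"` fixes phi = 0 on all outer surfaces
#' (distant return electrode); `"insulating"` imposes zero flux with a
#' single reference node pinned to 0; `"fixed"` imposes caller-supplied
#' `boundary_values` (used e.g. to match an analytic far field).
#'
#' @param placement a `cuff_placement`
#' @param contact contact index
#' @param cmap a `conductivity_map`
#' @param grid a `grid_spec`
#' @param boundary `"grounded"`, `"insulating"`, or `"fixed"`
#' @param boundary_values function(coords) -> V, required for `"fixed"`
#' @param tol relative residual tolerance (default 1e-8)
#' @param maxit conjugate-gradient iteration cap
#' @return an object of class `grid_solution` with the potential array
#'   `phi` (V), face conductance arrays, source node index, and
#'   convergence metadata
#' @export
solve_basis_fd <- function(placement, contact, cmap, grid,
                           boundary = c("grounded", "insulating", "fixed"),
                           boundary_values = NULL,
                           tol = 1e-8, maxit = 5000L) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(placement, "cuff_placement"),
            inherits(cmap, "conductivity_map"),
            inherits(grid, "grid_spec"))
  out <- solve_fd_multi(placement$source_points[contact, , drop = FALSE],
                        1, cmap, grid, boundary, boundary_values, tol,
                        maxit)
  out$contact_index <- as.integer(contact)
  out
}

# direct multi-source FD solve: one assembled system, several injections.
# Used both as the basis solver (single 1 mA source) and as the direct
# two-source oracle against weighted basis superposition.
solve_fd_multi <- function(sources, currents_mA, cmap, grid,
                           boundary = "grounded", boundary_values = NULL,
                           tol = 1e-8, maxit = 5000L) {
  sources <- rbind(sources)
  stopifnot(nrow(sources) == length(currents_mA))
  ax <- grid_axes(grid)
  nx <- grid$shape[1]; ny <- grid$shape[2]; nz <- grid$shape[3]
  nn <- nx * ny * nz
  h_m <- grid$spacing * 1e-6

  sig <- build_sigma_arrays(cmap, grid)

  # face conductances (S): harmonic-mean conductivity times face area over
  # cell pitch
  harm <- function(a, b) 2 * a * b / (a + b)
  Gx <- harm(sig[[1]][-nx, , , drop = FALSE],
             sig[[1]][-1, , , drop = FALSE]) * h_m[2] * h_m[3] / h_m[1]
  Gy <- harm(sig[[2]][, -ny, , drop = FALSE],
             sig[[2]][, -1, , drop = FALSE]) * h_m[1] * h_m[3] / h_m[2]
  Gz <- harm(sig[[3]][, , -nz, drop = FALSE],
             sig[[3]][, , -1, drop = FALSE]) * h_m[1] * h_m[2] / h_m[3]

  # perineurium thin layers: extra series resistance on crossing faces
  if (length(cmap$thin_layers)) {
    xy <- cbind(rep(ax[[1]], times = ny), rep(ax[[2]], each = nx))
    for (tl in cmap$thin_layers) {
      if (tl$rho_s <= 0) next
      ins <- matrix(points_in_trace(xy, tl$trace), nx, ny)
      kz <- if (is.null(tl$z_extent)) seq_len(nz)
            else which(ax[[3]] >= min(tl$z_extent) & ax[[3]] <= max(tl$z_extent))
      R_extra_x <- tl$rho_s / (h_m[2] * h_m[3])
      R_extra_y <- tl$rho_s / (h_m[1] * h_m[3])
      cx <- which(ins[-nx, ] != ins[-1, ])      # x-crossing faces (2D index)
      cy <- which(ins[, -ny] != ins[, -1])
      for (z in kz) {
        if (length(cx)) {
          idx <- cx + (z - 1L) * (nx - 1L) * ny
          Gx[idx] <- 1 / (1 / Gx[idx] + R_extra_x)
        }
        if (length(cy)) {
          idx <- cy + (z - 1L) * nx * (ny - 1L)
          Gy[idx] <- 1 / (1 / Gy[idx] + R_extra_y)
        }
      }
    }
  }

  # source nodes (nearest grid node per injection point)
  node3 <- t(apply(sources, 1L, function(p)
    vapply(1:3, function(k) which.min(abs(ax[[k]] - p[k])), 1L)))
  if (boundary != "insulating" &&
      any(node3 == 1L | sweep(node3, 2, grid$shape, `==`)))
    stop("source point falls on a boundary node")
  src_ids <- node3[, 1] + (node3[, 2] - 1L) * nx + (node3[, 3] - 1L) * nx * ny
  ii <- node3[1L, ]

  # unknown mask
  if (boundary == "insulating") {
    fixed <- rep(FALSE, nn)
    fixed[1L] <- TRUE   # reference node
    phi_fixed <- numeric(nn)
  } else {
    im <- array(FALSE, dim = grid$shape)
    im[c(1, nx), , ] <- TRUE; im[, c(1, ny), ] <- TRUE; im[, , c(1, nz)] <- TRUE
    fixed <- as.vector(im)
    phi_fixed <- numeric(nn)
    if (boundary == "fixed") {
      if (is.null(boundary_values))
        stop("boundary = 'fixed' needs boundary_values(coords)")
      bidx <- which(fixed)
      coords <- cbind(ax[[1]][(bidx - 1L) %% nx + 1L],
                      ax[[2]][((bidx - 1L) %/% nx) %% ny + 1L],
                      ax[[3]][(bidx - 1L) %/% (nx * ny) + 1L])
      phi_fixed[bidx] <- boundary_values(coords)
    }
  }
  if (any(fixed[src_ids])) stop("source node is a fixed boundary node")

  # assemble face lists: (node a, node b, conductance)
  face_ids <- function(G, d) {
    dm <- dim(G)
    idx <- which(G > -Inf)  # all faces
    a3 <- arrayInd(idx, dm)
    a <- a3[, 1] + (a3[, 2] - 1L) * nx + (a3[, 3] - 1L) * nx * ny
    b <- a
    if (d == 1L) b <- a + 1L
    if (d == 2L) b <- a + nx
    if (d == 3L) b <- a + nx * ny
    list(a = a, b = b, g = as.vector(G))
  }
  fx <- face_ids(Gx, 1L); fy <- face_ids(Gy, 2L); fz <- face_ids(Gz, 3L)
  fa <- c(fx$a, fy$a, fz$a); fb <- c(fx$b, fy$b, fz$b)
  fg <- c(fx$g, fy$g, fz$g)

  unk <- which(!fixed)
  newid <- integer(nn); newid[unk] <- seq_along(unk)
  b_rhs <- numeric(length(unk))
  for (s in seq_len(nrow(sources)))
    b_rhs[newid[src_ids[s]]] <- b_rhs[newid[src_ids[s]]] +
      1e-3 * currents_mA[s]

  a_un <- !fixed[fa]; b_un <- !fixed[fb]
  both <- a_un & b_un
  # off-diagonals
  i_off <- c(newid[fa[both]], newid[fb[both]])
  j_off <- c(newid[fb[both]], newid[fa[both]])
  x_off <- c(-fg[both], -fg[both])
  # diagonal accumulations: every face touching an unknown node
  i_diag <- c(newid[fa[a_un]], newid[fb[b_un]])
  x_diag <- c(fg[a_un], fg[b_un])
  # Dirichlet neighbor contributions to RHS
  ab <- a_un & !b_un
  ba <- b_un & !a_un
  if (any(ab)) b_rhs <- b_rhs + tabulate0(newid[fa[ab]],
                                          fg[ab] * phi_fixed[fb[ab]],
                                          length(unk))
  if (any(ba)) b_rhs <- b_rhs + tabulate0(newid[fb[ba]],
                                          fg[ba] * phi_fixed[fa[ba]],
                                          length(unk))

  A <- Matrix::sparseMatrix(i = c(i_off, i_diag), j = c(j_off, i_diag),
                            x = c(x_off, x_diag),
                            dims = c(length(unk), length(unk)))

  sol <- pcg(A, b_rhs, tol = tol, maxit = maxit)
  phi <- phi_fixed
  phi[unk] <- sol$x
  if (boundary == "insulating") phi <- phi - phi[1L]

  structure(list(origin = grid$origin, spacing = grid$spacing,
                 shape = grid$shape,
                 phi = array(phi, dim = grid$shape),
                 Gx = Gx, Gy = Gy, Gz = Gz,
                 source_node = ii, contact_index = NA_integer_,
                 boundary = boundary,
                 iterations = sol$iterations, residual = sol$residual,
                 current_mA = sum(currents_mA)),
            class = "grid_solution")
}

# direct two-source oracle for the superposition tests
fd_two_source_direct <- function(placement, cmap, grid, weights,
                                 tol = 1e-10) {
  solve_fd_multi(placement$source_points, weights, cmap, grid,
                 boundary = "grounded", tol = tol)
}

tabulate0 <- function(i, x, n) {
  out <- numeric(n)
  s <- rowsum(x, i)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

# Jacobi-preconditioned conjugate gradients
pcg <- function(A, b, tol = 1e-8, maxit = 5000L) {
  d <- Matrix::diag(A)
  x <- numeric(length(b))
  r <- b
  z <- r / d
  p <- z
  rz <- sum(r * z)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) return(list(x = x, iterations = 0L, residual = 0))
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    res <- sqrt(sum(r^2)) / bnorm
    if (res <= tol) return(list(x = x, iterations = it, residual = res))
    z <- r / d
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  stop(sprintf("conjugate gradients did not converge in %d iterations (residual %.2e)",
               maxit, res))
}

#' @exportS3Method base::print
print.grid_solution <- function(x, ...) {
  cat(sprintf("<grid_solution> %dx%dx%d, h=%g um, %s boundary, %d CG iters, residual %.1e\n",
              x$shape[1], x$shape[2], x$shape[3], max(x$spacing), x$boundary,
              x$iterations, x$residual))
  invisible(x)
}

#' Net current leaving a node box around a point (flux audit)
#'
#' Sums the discrete face currents G_f (phi_in - phi_out) over the surface
#' of the node box extending `margin` cells around the source node. For a
#' converged solution this equals the injected current.
#'
#' @param gs a `grid_solution`
#' @param margin half-width of the box in cells (default 2)
#' @return net outward current in mA
#' @export
box_outflux <- function(gs, margin = 2L) {
  ii <- gs$source_node
  lo <- pmax(ii - margin, 2L)
  hi <- pmin(ii + margin, gs$shape - 1L)
  phi <- gs$phi
  total <- 0
  # x faces: between (lo[1]-1, lo[1]) and (hi[1], hi[1]+1)
  js <- lo[2]:hi[2]; ks <- lo[3]:hi[3]
  total <- total +
    sum(gs$Gx[lo[1] - 1L, js, ks] * (phi[lo[1], js, ks] - phi[lo[1] - 1L, js, ks])) +
    sum(gs$Gx[hi[1], js, ks] * (phi[hi[1], js, ks] - phi[hi[1] + 1L, js, ks]))
  is <- lo[1]:hi[1]
  total <- total +
    sum(gs$Gy[is, lo[2] - 1L, ks] * (phi[is, lo[2], ks] - phi[is, lo[2] - 1L, ks])) +
    sum(gs$Gy[is, hi[2], ks] * (phi[is, hi[2], ks] - phi[is, hi[2] + 1L, ks]))
  total <- total +
    sum(gs$Gz[is, js, lo[3] - 1L] * (phi[is, js, lo[3]] - phi[is, js, lo[3] - 1L])) +
    sum(gs$Gz[is, js, hi[3]] * (phi[is, js, hi[3]] - phi[is, js, hi[3] + 1L]))
  total * 1e3  # A -> mA
}

#' Superpose basis fields by contact weights
#'
#' Potentials scale linearly with injected current, so the field of any
#' contact weighting is the dot product of the 1 mA bases with the weight
#' vector.
#'
#' @param bases list of `basis_field` / `grid_solution` objects (one per
#'   contact, same solver and grid)
#' @param weights numeric contact currents (mA)
#' @return an object of class `superposed_field`
#' @export
superpose <- function(bases, weights) {
  if (length(bases) != length(weights))
    stop("one weight per basis is required")
  cls <- vapply(bases, function(b) class(b)[1], "")
  if (length(unique(cls)) != 1L)
    stop("all bases must come from the same solver")
  structure(list(bases = bases, weights = as.numeric(weights)),
            class = "superposed_field")
}

#' Sample a field's potentials at fiber coordinates
#'
#' Analytic fields are evaluated exactly; grid solutions are trilinearly
#' interpolated. Output order matches input order.
#'
#' @param field a `basis_field`, `grid_solution`, or `superposed_field`
#' @param coords n x 3 matrix (x, y, z) in um
#' @return numeric vector of potentials (V)
#' @export
sample_potentials <- function(field, coords) {
  coords <- rbind(coords)
  UseMethod("sample_potentials")
}

#' @export
sample_potentials.basis_field <- function(field, coords)
  eval_analytic(field, coords)

#' @export
sample_potentials.superposed_field <- function(field, coords) {
  out <- numeric(nrow(rbind(coords)))
  for (k in seq_along(field$bases))
    out <- out + field$weights[k] * sample_potentials(field$bases[[k]], coords)
  out
}

#' @export
sample_potentials.grid_solution <- function(field, coords) {
  coords <- rbind(coords)
  g <- field
  u <- sweep(sweep(coords, 2, g$origin), 2, g$spacing, `/`)  # 0-based frac index
  n <- g$shape
  if (any(u < -1e-9) || any(t(u) > n - 1 + 1e-9))
    stop("coordinate outside the solver grid")
  u <- pmax(u, 0)
  i0 <- pmin(floor(u[, 1]), n[1] - 2); fx <- u[, 1] - i0
  j0 <- pmin(floor(u[, 2]), n[2] - 2); fy <- u[, 2] - j0
  k0 <- pmin(floor(u[, 3]), n[3] - 2); fz <- u[, 3] - k0
  id <- function(i, j, k) 1L + i + j * n[1] + k * n[1] * n[2]
  p <- g$phi
  c000 <- p[id(i0, j0, k0)];     c100 <- p[id(i0 + 1, j0, k0)]
  c010 <- p[id(i0, j0 + 1, k0)]; c110 <- p[id(i0 + 1, j0 + 1, k0)]
  c001 <- p[id(i0, j0, k0 + 1)]; c101 <- p[id(i0 + 1, j0, k0 + 1)]
  c011 <- p[id(i0, j0 + 1, k0 + 1)]; c111 <- p[id(i0 + 1, j0 + 1, k0 + 1)]
  (c000 * (1 - fx) + c100 * fx) * (1 - fy) * (1 - fz) +
  (c010 * (1 - fx) + c110 * fx) * fy * (1 - fz) +
  (c001 * (1 - fx) + c101 * fx) * (1 - fy) * fz +
  (c011 * (1 - fx) + c111 * fx) * fy * fz
}

#' Super-sample a dense axial potential profile and re-interpolate
#'
#' `super_sample` evaluates a field on a dense z grid at one (x, y)
#' location, centered on `z_center`, so later fiber discretizations can be
#' served by linear interpolation without re-querying the solver. The
#' profile can be cached as a two-column text file (z, V).
#'
#' @param field any field accepted by [sample_potentials()]
#' @param xy length-2 (x, y) um
#' @param dz_ss super-sampling step (um); must not exceed the smallest
#'   target compartment spacing
#' @param length axial extent (um)
#' @param z_center profile center (um)
#' @param cache_dir optional directory; profiles are stored as
#'   `ss_<hash>.dat` and reused when the same field/xy/grid is requested
#' @return matrix with columns `z` (um) and `V` (volts)
#' @export
super_sample <- function(field, xy, dz_ss, length, z_center = 0,
                         cache_dir = NULL) {
  stopifnot(dz_ss > 0, length > 0)
  z <- seq(z_center - length / 2, z_center + length / 2, by = dz_ss)
  key <- NULL
  if (!is.null(cache_dir)) {
    key <- object_hash(list(field, xy, dz_ss, length, z_center))
    f <- file.path(cache_dir, paste0("ss_", key, ".dat"))
    if (file.exists(f)) {
      m <- as.matrix(utils::read.table(f, header = TRUE))
      colnames(m) <- c("z", "V")
      return(m)
    }
  }
  V <- sample_potentials(field, cbind(xy[1], xy[2], z))
  m <- cbind(z = z, V = V)
  if (!is.null(key)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(as.data.frame(m), file.path(cache_dir,
                                                   paste0("ss_", key, ".dat")),
                       row.names = FALSE, quote = FALSE)
  }
  m
}

#' @rdname super_sample
#' @param profile a matrix from [super_sample()]
#' @param target_z fiber compartment z coordinates (um)
#' @return interpolated potentials (V) at `target_z`
#' @export
interp_to_fiber <- function(profile, target_z) {
  if (min(target_z) < min(profile[, 1]) - 1e-9 ||
      max(target_z) > max(profile[, 1]) + 1e-9)
    stop("target z outside the super-sampled profile extent")
  stats::approx(profile[, 1], profile[, 2], xout = target_z, rule = 1)$y
}

# stable content hash without external digest dependency
object_hash <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(obj, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
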