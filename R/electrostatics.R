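# Quasi-static electric potential and the DEP drive field grad|E|^2.
#
# The spatial problem div(sigma grad V) = 0 is solved once with the
# electrode amplitudes +-Va (alternating polarity); the signal frequency
# enters only through the Clausius-Mossotti factor. Insulating (zero
# normal current) conditions hold on every non-electrode boundary.

#' Solve the electric potential problem
#'
#' Laplace problem with Dirichlet values +-Va on the exposed faces of each
#' electrode notch (alternating polarity per the drive pattern) and zero
#' normal current elsewhere.
#'
#' @param mesh A [generate_mesh()] result carrying at least two
#'   `electrode_*` boundary tags.
#' @param drive An [electrode_drive()].
#' @param medium A [medium_props()] (conductivity used for the current
#'   density J = sigma E).
#' @return Object of class `potential_solution`: P2 potential `V` (volts),
#'   recovered nodal fields `e2` (|E|^2, V^2/um^2) and `gx`, `gy`
#'   (grad|E|^2, V^2/um^3), plus sampling support.
#' @export
solve_potential <- function(mesh, drive, medium = medium_props()) {
  stopifnot(inherits(mesh, "loc_mesh"), inherits(drive, "electrode_drive"))
  etags <- sort(grep("^electrode_", unique(mesh$boundary$tag), value = TRUE))
  if (length(etags) < 2)
    stop("configuration error: the mesh carries fewer than 2 electrode tags")
  if (length(etags) != drive$n_electrodes)
    stop("configuration error: drive defines ", drive$n_electrodes,
         " electrodes but the mesh carries ", length(etags))
  st <- p2_structure(mesh)
  geom <- tri_geometry(mesh)
  K <- assemble_p2_stiffness(mesh, st, geom)
  fix <- integer(0); vals <- numeric(0)
  for (k in seq_along(etags)) {
    d <- boundary_p2_dofs(mesh, st, etags[k])
    fix <- c(fix, d)
    vals <- c(vals, rep(drive$pattern[k] * drive$amplitude_V, length(d)))
  }
  # shared corner dofs between adjacent electrodes cannot occur (the
  # notches are separated by wall segments), but guard against duplicates
  dup <- duplicated(fix)
  fix <- fix[!dup]; vals <- vals[!dup]
  V <- solve_with_dirichlet(K, numeric(st$n_dof), fix, vals)
  out <- potential_postprocess(mesh, st, geom, V)
  out$drive <- drive; out$medium <- medium
  out
}

# recovery pipeline shared by the solver and by manufactured-field tests:
# |E|^2 evaluated per element at its corners -> area-weighted nodal
# recovery -> element-wise gradient of the recovered P1 field -> second
# nodal recovery
potential_postprocess <- function(mesh, st, geom, V) {
  m <- nrow(mesh$tri)
  Vloc <- matrix(V[st$tri_dofs], ncol = 6)
  e2 <- matrix(0, m, 3); ex <- matrix(0, m, 3); ey <- matrix(0, m, 3)
  corners <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  for (k in 1:3) {
    C <- p2_grad_coef(corners[k, ])
    dVx <- rowSums(Vloc * (geom$gx %*% t(C)))
    dVy <- rowSums(Vloc * (geom$gy %*% t(C)))
    e2[, k] <- dVx^2 + dVy^2
    ex[, k] <- -dVx
    ey[, k] <- -dVy
  }
  e2_node <- nodal_recovery(mesh, e2, geom$area)
  ex_node <- nodal_recovery(mesh, ex, geom$area)
  ey_node <- nodal_recovery(mesh, ey, geom$area)
  # element-constant gradient of the P1-recovered |E|^2, recovered again
  tr <- mesh$tri
  e2v <- matrix(e2_node[tr], ncol = 3)
  gxe <- rowSums(e2v * geom$gx)
  gye <- rowSums(e2v * geom$gy)
  gx_node <- nodal_recovery(mesh, gxe, geom$area)
  gy_node <- nodal_recovery(mesh, gye, geom$area)
  structure(list(mesh = mesh, st = st, V = V,
                 e2 = e2_node, ex = ex_node, ey = ey_node,
                 gx = gx_node, gy = gy_node,
                 locator = build_locator(mesh)),
            class = "potential_solution")
}

#' Build a potential solution from prescribed values
#'
#' Interpolates an arbitrary potential (function of x, y in um, or a P2
#' coefficient vector) onto the mesh and runs the same |E|^2 / grad|E|^2
#' recovery as [solve_potential()]. Used for manufactured-field
#' verification.
#'
#' @param mesh A [generate_mesh()] result.
#' @param values `function(x, y)` in volts, or a numeric P2 coefficient
#'   vector.
#' @return A `potential_solution`.
#' @export
potential_from_values <- function(mesh, values) {
  st <- p2_structure(mesh)
  geom <- tri_geometry(mesh)
  V <- if (is.function(values))
    values(st$dof_coords[, 1], st$dof_coords[, 2])
  else values
  stopifnot(length(V) == st$n_dof)
  potential_postprocess(mesh, st, geom, V)
}

#' @exportS3Method base::print
print.potential_solution <- function(x, ...) {
  cat(sprintf("<potential_solution>  V range [%.3g, %.3g] V, max |E| = %.3g V/um\n",
              min(x$V), max(x$V), sqrt(max(x$e2))))
  invisible(x)
}

#' Sample potential, field and DEP drive at points
#'
#' @param sol A [solve_potential()] result.
#' @param points `c(x, y)` or n x 2 matrix, um.
#' @return data.frame with `V`, `Ex_V_m`, `Ey_V_m`, `e2_V2_m2` and the DEP
#'   drive components `gx_V2_m3`, `gy_V2_m3` (grad|E|^2 in SI units).
#' @export
sample_potential <- function(sol, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  loc <- locate_points(sol$locator, points)
  if (anyNA(loc$tri)) {
    i <- which(is.na(loc$tri))[1]
    stop("out-of-domain: point (", points[i, 1], ", ", points[i, 2],
         ") lies outside the meshed geometry")
  }
  data.frame(V = eval_p2(sol$st, sol$V, loc),
             Ex_V_m = eval_p1(sol$mesh, sol$ex, loc) * 1e6,
             Ey_V_m = eval_p1(sol$mesh, sol$ey, loc) * 1e6,
             e2_V2_m2 = eval_p1(sol$mesh, sol$e2, loc) * 1e12,
             gx_V2_m3 = eval_p1(sol$mesh, sol$gx, loc) * 1e18,
             gy_V2_m3 = eval_p1(sol$mesh, sol$gy, loc) * 1e18)
}

#' The DEP drive field grad|E|^2
#'
#' Returns the patchwise-recovered gradient of the squared field magnitude
#' with an evaluation contract at arbitrary interior points.
#'
#' @param sol A [solve_potential()] result.
#' @return Object of class `dep_drive_field`; evaluate with
#'   [sample_drive()].
#' @export
dep_drive_field <- function(sol) {
  structure(list(sol = sol), class = "dep_drive_field")
}

#' Evaluate a DEP drive field
#'
#' @param drive_field A [dep_drive_field()].
#' @param points `c(x, y)` or n x 2 matrix, um.
#' @return n x 2 matrix of grad|E|^2 in V^2/m^3.
#' @export
sample_drive <- function(drive_field, points) {
  s <- sample_potential(drive_field$sol, points)
  cbind(s$gx_V2_m3, s$gy_V2_m3)
}
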