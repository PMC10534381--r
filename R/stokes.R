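# Steady incompressible creeping (Stokes) flow on the meshed device.
#
# Weak form: mu * (grad u, grad v) - (p, div v) = 0, (q, div u) = 0, with
# no-slip walls/electrodes, imposed inlet velocity, and the do-nothing
# outflow condition (-p I + mu grad u) . n = 0 on the outlet faces, which
# realizes the 0 Pa static outlet pressure of the device. Velocities are
# carried in um/s and pressure in Pa (with coordinates in um the two
# Stokes blocks then need no unit factors).

#' Flow boundary conditions
#'
#' @param v_blood_um_s Mean inlet speed at the blood (upper) inlet, um/s.
#' @param v_buffer_um_s Mean inlet speed at the buffer (lower) inlet, um/s.
#' @param profile `"plug"` (uniform normal velocity at the stated mean,
#'   the default) or `"parabolic"` (fully developed profile with the same
#'   mean).
#' @return Object of class `flow_bc`. Outlet static pressure is fixed at
#'   0 Pa (do-nothing outflow); walls are no-slip.
#' @export
flow_bc <- function(v_blood_um_s, v_buffer_um_s = 0,
                    profile = c("plug", "parabolic")) {
  profile <- match.arg(profile)
  if (v_blood_um_s < 0 || v_buffer_um_s < 0)
    stop("inlet speeds must be >= 0")
  structure(list(v_blood_um_s = v_blood_um_s,
                 v_buffer_um_s = v_buffer_um_s,
                 outlet_pressure_Pa = 0, wall = "no-slip",
                 profile = profile),
            class = "flow_bc")
}

solid_tags <- function(mesh) {
  tags <- unique(mesh$boundary$tag)
  c("wall", grep("^electrode_", tags, value = TRUE))
}

# fractional position of P2 dofs along a tagged face
face_dof_positions <- function(mesh, st, tag) {
  fr <- mesh$geometry$frames[[tag]]
  dofs <- boundary_p2_dofs(mesh, st, tag)
  if (!length(dofs)) return(NULL)
  xy <- st$dof_coords[dofs, , drop = FALSE]
  d <- fr$p2 - fr$p1
  t <- ((xy[, 1] - fr$p1[1]) * d[1] + (xy[, 2] - fr$p1[2]) * d[2]) / sum(d^2)
  list(dofs = dofs, t = t, dir = fr$dir)
}

#' Solve steady creeping flow
#'
#' Taylor-Hood (quadratic velocity / linear pressure) discretization with a
#' direct sparse solve.
#'
#' @param mesh A [generate_mesh()] result with tagged inlet/outlet faces.
#' @param bc A [flow_bc()].
#' @param medium A [medium_props()] (viscosity is the only property used by
#'   the flow problem).
#' @return Object of class `flow_field` with P2 velocity coefficient
#'   vectors `ux`, `uy` (um/s), nodal P1 pressure `p` (Pa), and an
#'   interpolation contract via [sample_flow()].
#' @export
solve_stokes <- function(mesh, bc, medium = medium_props()) {
  stopifnot(inherits(mesh, "loc_mesh"), inherits(bc, "flow_bc"))
  st <- p2_structure(mesh)
  geom <- tri_geometry(mesh)
  mu <- medium$dynamic_viscosity_Pa_s
  K <- assemble_p2_stiffness(mesh, st, geom)
  Dv <- assemble_divergence(mesh, st, geom)
  nd <- st$n_dof; nv <- st$n_vertex
  S <- rbind(cbind(mu * K, Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                                x = numeric(0), dims = c(nd, nd)),
                   -Matrix::t(Dv$D1)),
             cbind(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                        x = numeric(0), dims = c(nd, nd)),
                   mu * K, -Matrix::t(Dv$D2)),
             cbind(-Dv$D1, -Dv$D2,
                   Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                        x = numeric(0), dims = c(nv, nv))))

  fix <- integer(0); vx <- numeric(0); vy <- numeric(0)
  solid <- boundary_p2_dofs(mesh, st, solid_tags(mesh))
  inlet_specs <- list(blood_inlet = bc$v_blood_um_s,
                      buffer_inlet = bc$v_buffer_um_s)
  inlet_dofs <- integer(0); inlet_vx <- numeric(0); inlet_vy <- numeric(0)
  for (tag in names(inlet_specs)) {
    if (!tag %in% names(mesh$geometry$frames)) next
    fp <- face_dof_positions(mesh, st, tag)
    if (is.null(fp)) next
    v <- inlet_specs[[tag]]
    mag <- if (bc$profile == "plug") rep(v, length(fp$dofs))
           else 6 * v * fp$t * (1 - fp$t)
    inlet_dofs <- c(inlet_dofs, fp$dofs)
    inlet_vx <- c(inlet_vx, mag * fp$dir[1])
    inlet_vy <- c(inlet_vy, mag * fp$dir[2])
  }
  solid <- setdiff(solid, inlet_dofs)   # inlet values win at shared corners
  fix_u <- c(solid, inlet_dofs)
  valx <- c(rep(0, length(solid)), inlet_vx)
  valy <- c(rep(0, length(solid)), inlet_vy)

  fix <- c(fix_u, fix_u + nd)
  vals <- c(valx, valy)
  sol <- tryCatch(
    solve_with_dirichlet(S, numeric(2 * nd + nv), fix, vals),
    error = function(e) stop("solver error: Stokes system could not be ",
                             "solved (singular or ill-posed; check outlet ",
                             "tagging): ", conditionMessage(e)))
  structure(list(mesh = mesh, st = st, geom = geom,
                 ux = sol[seq_len(nd)], uy = sol[nd + seq_len(nd)],
                 p = sol[2 * nd + seq_len(nv)],
                 bc = bc, medium = medium,
                 locator = build_locator(mesh)),
            class = "flow_field")
}

#' @exportS3Method base::print
print.flow_field <- function(x, ...) {
  cat(sprintf("<flow_field>  %d velocity dofs, |u|max = %.3g um/s, p range [%.3g, %.3g] Pa\n",
              2 * x$st$n_dof, max(sqrt(x$ux^2 + x$uy^2)),
              min(x$p), max(x$p)))
  invisible(x)
}

#' Sample the flow field at points
#'
#' Continuous interpolation (quadratic velocity, linear pressure); exact
#' nodal values at mesh nodes.
#'
#' @param flow A [solve_stokes()] result.
#' @param points Numeric vector `c(x, y)` or an n x 2 matrix, um.
#' @return data.frame with `ux_um_s`, `uy_um_s`, `p_Pa`.
#' @export
sample_flow <- function(flow, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  loc <- locate_points(flow$locator, points)
  if (anyNA(loc$tri)) {
    i <- which(is.na(loc$tri))[1]
    stop("out-of-domain: point (", points[i, 1], ", ", points[i, 2],
         ") lies outside the meshed geometry")
  }
  data.frame(ux_um_s = eval_p2(flow$st, flow$ux, loc),
             uy_um_s = eval_p2(flow$st, flow$uy, loc),
             p_Pa = eval_p1(flow$mesh, flow$p, loc))
}

#' Signed flux through a tagged inlet/outlet face
#'
#' Line integral of u . n over the face (Simpson rule on each boundary
#' edge, exact for the quadratic trace), positive along the face's flow
#' direction (into the domain at inlets, out of it at outlets).
#'
#' @param flow A [solve_stokes()] result.
#' @param tag Face tag (one of the inlet/outlet tags).
#' @return Flux in um^2/s.
#' @export
boundary_flux <- function(flow, tag) {
  mesh <- flow$mesh
  fr <- mesh$geometry$frames[[tag]]
  if (is.null(fr)) stop("unknown face tag: ", tag)
  b <- mesh$boundary[mesh$boundary$tag == tag, , drop = FALSE]
  if (nrow(b) == 0) stop("no boundary edges carry tag ", tag)
  st <- flow$st
  nv <- st$n_vertex
  key <- pmin(b$n1, b$n2) + pmax(b$n1, b$n2) * (nv + 1)
  emid <- nv + match(key, st$edge_key)
  p1 <- mesh$nodes[b$n1, , drop = FALSE]; p2 <- mesh$nodes[b$n2, , drop = FALSE]
  len <- sqrt(rowSums((p2 - p1)^2))
  un <- function(d) flow$ux[d] * fr$dir[1] + flow$uy[d] * fr$dir[2]
  sum(len / 6 * (un(b$n1) + 4 * un(emid) + un(b$n2)))
}
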