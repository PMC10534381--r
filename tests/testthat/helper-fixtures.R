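# Shared fixtures, built once per test run. Kept deliberately small:
# coarse meshes for behavioural checks, fine meshes only where an
# analytic oracle demands the accuracy.

EPS0_TEST <- 8.854187817e-12

# independent shoelace area oracle (kept separate from the package's own)
oracle_shoelace <- function(pts) {
  n <- nrow(pts)
  j <- c(2:n, 1)
  abs(sum(pts[, 1] * pts[j, 2] - pts[j, 1] * pts[, 2])) / 2
}

# independent even-odd point-in-polygon oracle
oracle_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (k in seq_len(n)) {
    xi <- poly[k, 1]; yi <- poly[k, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > y) != (yj > y) &&
        x < (xj - xi) * (y - yi) / (yj - yi) + xi) inside <- !inside
    j <- k
  }
  inside
}

fix <- new.env()

loc_geom <- function() {
  if (is.null(fix$geom)) fix$geom <- build_loc_geometry(loc_params())
  fix$geom
}

loc_mesh_coarse <- function() {
  if (is.null(fix$mesh_coarse))
    fix$mesh_coarse <- generate_mesh(loc_geom(), "coarse")
  fix$mesh_coarse
}

loc_mesh_normal <- function() {
  if (is.null(fix$mesh_normal))
    fix$mesh_normal <- generate_mesh(loc_geom(), "normal")
  fix$mesh_normal
}

# flow + potential on the normal mesh at the reference operating point
loc_flow_normal <- function() {
  if (is.null(fix$flow_normal))
    fix$flow_normal <- solve_stokes(loc_mesh_normal(), flow_bc(134, 850))
  fix$flow_normal
}

loc_potential_normal <- function() {
  if (is.null(fix$pot_normal))
    fix$pot_normal <- solve_potential(loc_mesh_normal(),
                                      electrode_drive(2, 4))
  fix$pot_normal
}

# per-species mean distance from the electrode-side wall at the end of
# the active stage (the Fig-9-style alpha/beta/gamma trajectory gaps):
# CW - y interpolated where each path last crosses x = xJ2
stage1_gaps <- function(trajectories, geometry) {
  CW <- geometry$params$channel_width_um
  xs <- geometry$layout$xJ2
  gap_one <- function(tr) {
    p <- tr$path
    i <- which(p[-nrow(p), "x_um"] < xs & p[-1, "x_um"] >= xs)
    if (!length(i)) return(NA_real_)
    i <- i[length(i)]
    f <- (xs - p[i, "x_um"]) / (p[i + 1, "x_um"] - p[i, "x_um"])
    CW - (p[i, "y_um"] + f * (p[i + 1, "y_um"] - p[i, "y_um"]))
  }
  gaps <- vapply(trajectories, gap_one, numeric(1))
  sp <- vapply(trajectories, function(t) t$species, character(1))
  vapply(c(CTC = "CTC", WBC = "WBC", PLT = "PLT"),
         function(s) mean(gaps[sp == s], na.rm = TRUE), numeric(1))
}
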