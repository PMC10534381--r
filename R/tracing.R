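# Lagrangian cell tracing through the solved flow and potential fields.
#
# Default dynamics are overdamped (point-particle mobility): the Stokes
# relaxation time of a <= 15 um cell in an aqueous buffer (~1e-5 s) is
# negligible against the seconds-long transit, so
#   dx/dt = u(x) + F_DEP(x) / (6 pi mu Rp).
# An inertial mode integrating m dv/dt = 6 pi mu Rp (u - v) + F_DEP is
# kept for sensitivity checks. Integration uses an embedded Cash-Karp
# Runge-Kutta 4(5) scheme with adaptive step control; trajectories end on
# outlet crossing, wall contact (centre closer than Rp to a solid
# boundary) or at t_end.

TARGET_OUTLETS <- c(CTC = "outlet_CTC", WBC = "outlet_WBC",
                    PLT = "outlet_PLT")

#' Tracer settings
#'
#' @param t_end_s Simulation window, s (default 8).
#' @param rel_tol Relative tolerance of the adaptive integrator, in
#'   (0, 1e-3].
#' @param mode `"overdamped"` (default) or `"inertial"`.
#' @param max_step_s Upper bound on the time step, s.
#' @param cell_density_kg_m3 Cell density (inertial mode only).
#' @param contact Wall-contact model at centre distance < Rp from a solid
#'   boundary: `"slide"` (default; rigid-sphere excluded volume, the cell
#'   slides frictionlessly at one radius from the boundary) or `"freeze"`
#'   (the cell is immobilized on contact and counts as lost). See the
#'   methods vignette for the choice of default.
#' @return Object of class `tracer_settings`.
#' @export
tracer_settings <- function(t_end_s = 8, rel_tol = 1e-6,
                            mode = c("overdamped", "inertial"),
                            max_step_s = 0.02,
                            cell_density_kg_m3 = 1050,
                            contact = c("slide", "freeze")) {
  mode <- match.arg(mode)
  contact <- match.arg(contact)
  if (t_end_s <= 0) stop("t_end_s must be > 0")
  if (rel_tol <= 0 || rel_tol > 1e-3)
    stop("rel_tol must lie in (0, 1e-3]")
  structure(list(t_end_s = t_end_s, rel_tol = rel_tol, mode = mode,
                 max_step_s = max_step_s,
                 cell_density_kg_m3 = cell_density_kg_m3,
                 contact = contact),
            class = "tracer_settings")
}

# Cash-Karp tableau
CK <- list(
  a = c(0, 1/5, 3/10, 3/5, 1, 7/8),
  b = list(numeric(0), 1/5, c(3/40, 9/40), c(3/10, -9/10, 6/5),
           c(-11/54, 5/2, -70/27, 35/27),
           c(1631/55296, 175/512, 575/13824, 44275/110592, 253/4096)),
  c5 = c(37/378, 0, 250/621, 125/594, 0, 512/1771),
  c4 = c(2825/27648, 0, 18575/48384, 13525/55296, 277/14336, 1/4))

# fast single-point evaluator shared by the tracer: returns velocity
# (um/s) and drive (V^2/um^3) or NULL if outside
make_field_eval <- function(flow, potential) {
  loc <- flow$locator
  st <- flow$st
  tri <- flow$mesh$tri
  has_pot <- !is.null(potential)
  function(x, y) {
    ix <- floor((x - loc$bb[["xmin"]]) / loc$cs) + 1
    iy <- floor((y - loc$bb[["ymin"]]) / loc$cs) + 1
    if (is.na(ix) || ix < 1 || ix > loc$nx || iy < 1 || iy > loc$ny)
      return(NULL)
    cand <- loc$cells[[(iy - 1) * loc$nx + ix]]
    if (is.null(cand)) return(NULL)
    dx <- x - loc$x1[cand]; dy <- y - loc$y1[cand]
    l2 <- loc$b11[cand] * dx + loc$b12[cand] * dy
    l3 <- loc$b21[cand] * dx + loc$b22[cand] * dy
    l1 <- 1 - l2 - l3
    ok <- which(l1 >= -1e-9 & l2 >= -1e-9 & l3 >= -1e-9)
    if (!length(ok)) return(NULL)
    j <- ok[1]
    if (length(ok) > 1) j <- ok[which.max(pmin(l1[ok], l2[ok], l3[ok]))]
    t <- cand[j]
    lam <- c(l1[j], l2[j], l3[j])
    N <- c(lam * (2 * lam - 1), 4 * lam[1] * lam[2], 4 * lam[2] * lam[3],
           4 * lam[3] * lam[1])
    d <- st$tri_dofs[t, ]
    ux <- sum(N * flow$ux[d]); uy <- sum(N * flow$uy[d])
    if (has_pot) {
      vids <- tri[t, ]
      gx <- sum(lam * potential$gx[vids])
      gy <- sum(lam * potential$gy[vids])
    } else {
      gx <- 0; gy <- 0
    }
    c(ux, uy, gx, gy)
  }
}

# nearest point on the solid boundary (walls + electrode faces):
# returns c(squared distance, px, py)
make_wall_proj <- function(geometry) {
  solid <- geometry$edges[geometry$edges$tag == "wall" |
                            grepl("^electrode_", geometry$edges$tag), ]
  p1x <- solid$x1; p1y <- solid$y1
  dxs <- solid$x2 - solid$x1; dys <- solid$y2 - solid$y1
  len2 <- dxs^2 + dys^2
  function(x, y) {
    t <- ((x - p1x) * dxs + (y - p1y) * dys) / len2
    t <- pmin(1, pmax(0, t))
    px <- p1x + t * dxs; py <- p1y + t * dys
    d2 <- (x - px)^2 + (y - py)^2
    i <- which.min(d2)
    c(d2[i], px[i], py[i])
  }
}

# crossing of the chord (x0,y0)->(x1,y1) with outlet face segments;
# returns list(tag, s) for the earliest crossing or NULL
outlet_crossing <- function(frames, x0, y0, x1, y1) {
  best <- NULL
  for (tag in names(frames)) {
    if (!startsWith(tag, "outlet_")) next
    fr <- frames[[tag]]
    ex <- fr$p2[1] - fr$p1[1]; ey <- fr$p2[2] - fr$p1[2]
    dx <- x1 - x0; dy <- y1 - y0
    den <- dx * ey - dy * ex
    if (abs(den) < 1e-14) next
    s <- ((fr$p1[1] - x0) * ey - (fr$p1[2] - y0) * ex) / den
    u <- ((fr$p1[1] - x0) * dy - (fr$p1[2] - y0) * dx) / den
    if (s >= 0 && s <= 1 && u >= -1e-9 && u <= 1 + 1e-9) {
      if (is.null(best) || s < best$s) best <- list(tag = tag, s = s)
    }
  }
  best
}

#' Trace cell trajectories under drag and DEP
#'
#' Integrates every particle of the ensemble through the solved fields and
#' terminates each trajectory on outlet crossing, wall contact or at
#' `t_end`.
#'
#' @param flow A [solve_stokes()] result.
#' @param potential A [solve_potential()] result on the same mesh, or
#'   `NULL` for zero drive (pure advection).
#' @param ensemble A [generate_ensemble()] result.
#' @param medium A [medium_props()].
#' @param drive The [electrode_drive()] used (supplies the signal
#'   frequency for Re K); may be `NULL` when `potential` is `NULL`.
#' @param settings A [tracer_settings()].
#' @return Object of class `trajectory_set`: list of per-particle records
#'   with `id`, `species`, `status` (`exited`, `frozen_at_wall`,
#'   `unresolved_at_t_end`), `outlet` (tag or `NA`), `exit_time_s`,
#'   `exit_speed_um_s`, and the time series `path` (t, x, y, F_N).
#' @export
advance_particles <- function(flow, potential, ensemble,
                              medium = medium_props(), drive = NULL,
                              settings = tracer_settings()) {
  stopifnot(inherits(flow, "flow_field"),
            inherits(ensemble, "particle_ensemble"))
  if (!is.null(potential)) {
    if (!identical(dim(flow$mesh$nodes), dim(potential$mesh$nodes)) ||
        !isTRUE(all.equal(flow$mesh$nodes, potential$mesh$nodes)))
      stop("configuration error: flow and potential fields come from ",
           "mismatched meshes")
    if (is.null(drive))
      stop("configuration error: drive (signal frequency) required when ",
           "a potential is supplied")
  }
  geometry <- flow$mesh$geometry
  fev <- make_field_eval(flow, potential)
  wdist <- make_wall_proj(geometry)
  omega <- if (!is.null(drive)) drive$omega else 0
  mu <- medium$dynamic_viscosity_Pa_s

  # The potential is solved with the +-Va drive amplitudes; the force a
  # cell feels from the AC drive is the time average
  #   <F> = 2 pi eps_m Rp^3 Re K grad|E_rms|^2
  #       = 1/2 * 2 pi eps_m Rp^3 Re K grad|E_amp|^2,
  # hence the factor 1/2 on the amplitude-based drive field here.
  species <- unique(ensemble$species)
  coefs <- lapply(species, function(nm) {
    sp <- cell_species(nm)
    Rp <- sp$diameter_um / 2 * 1e-6
    K <- if (!is.null(potential)) species_cmf(sp, medium, omega) else 0
    pref_N <- 0.5 * 2 * pi * medium$rel_permittivity * EPS0 * Rp^3 * K * 1e18
    list(Rp_um = sp$diameter_um / 2, mu_Pa_s = mu,
         force_N_per_drive = pref_N,            # * drive[V^2/um^3] -> N
         drift_um_s_per_drive = pref_N / (6 * pi * mu * Rp) * 1e6)
  })
  names(coefs) <- species

  out <- vector("list", nrow(ensemble))
  for (i in seq_len(nrow(ensemble))) {
    cf <- coefs[[ensemble$species[i]]]
    out[[i]] <- trace_one(fev, wdist, geometry$frames,
                          c(ensemble$x[i], ensemble$y[i]),
                          ensemble$t_release_s[i], cf, settings)
    out[[i]]$id <- ensemble$id[i]
    out[[i]]$species <- ensemble$species[i]
  }
  structure(out, class = "trajectory_set")
}

trace_one <- function(fev, wdist, frames, x0, t0, cf, settings) {
  inertial <- settings$mode == "inertial"
  drift <- cf$drift_um_s_per_drive
  Fpref <- abs(cf$force_N_per_drive)
  if (inertial) {
    Rp_m <- cf$Rp_um * 1e-6
    mass <- settings$cell_density_kg_m3 * 4 / 3 * pi * Rp_m^3
    tau_inv <- 6 * pi * cf$mu_Pa_s * Rp_m / mass
  }
  # deriv returns d(state)/dt plus the local |F_DEP| and equilibrium speed
  deriv <- function(y) {
    f <- fev(y[1], y[2])
    if (is.null(f)) return(NULL)
    vx <- f[1] + drift * f[3]; vy <- f[2] + drift * f[4]
    Fmag <- Fpref * sqrt(f[3]^2 + f[4]^2)
    if (!inertial) {
      out <- c(vx, vy)
    } else {
      out <- c(y[3], y[4], tau_inv * (vx - y[3]), tau_inv * (vy - y[4]))
    }
    attr(out, "F") <- Fmag
    attr(out, "speed") <- if (!inertial) sqrt(vx^2 + vy^2)
                          else sqrt(y[3]^2 + y[4]^2)
    out
  }
  # speed/force at an exit point: the crossing point sits on the outlet
  # face itself, so sample a fixed small distance inside along the
  # approach chord (mesh-independent), falling back to the chord start
  exit_eval <- function(yc, chord, fallback) {
    u <- chord / max(sqrt(sum(chord^2)), 1e-12)
    for (back in c(0.25, 0.75, 2)) {
      d <- deriv(c(yc - back * u, rep(0, length(fallback) - 2)))
      if (!is.null(d)) return(d)
    }
    fallback
  }
  tol <- settings$rel_tol * 100   # um error scale per step
  t <- t0
  y <- x0
  if (inertial) {
    f0 <- fev(x0[1], x0[2])
    v0 <- if (!is.null(f0))
      c(f0[1] + drift * f0[3], f0[2] + drift * f0[4]) else c(0, 0)
    y <- c(x0, v0)
  }
  dt <- min(settings$max_step_s, 1e-3)
  slide <- settings$contact == "slide"
  Rp_c <- cf$Rp_um          # contact radius
  Rp2 <- Rp_c^2
  path <- list(c(t, y[1:2], 0))
  status <- "unresolved_at_t_end"; outlet <- NA_character_
  exit_t <- NA_real_; exit_speed <- NA_real_
  d_cur <- deriv(y)
  for (it in seq_len(200000L)) {
    if (t >= settings$t_end_s - 1e-12) break
    if (is.null(d_cur)) { status <- "frozen_at_wall"; break }
    dt <- min(dt, settings$t_end_s - t)
    k <- vector("list", 6)
    fail <- FALSE
    k[[1]] <- d_cur
    ys <- y
    for (s in 2:6) {
      ys <- y + dt * as.vector(Reduce(`+`, Map(`*`, CK$b[[s]], k[1:(s - 1)])))
      k[[s]] <- deriv(ys)
      if (is.null(k[[s]])) { fail <- TRUE; break }
    }
    if (fail) {
      # a failed stage point past an outlet face means the particle is
      # leaving through that outlet within this step
      cross <- outlet_crossing(frames, y[1], y[2], ys[1], ys[2])
      if (!is.null(cross)) {
        yc <- y + cross$s * (ys - y)
        dc <- exit_eval(yc[1:2], ys[1:2] - y[1:2], d_cur)
        status <- "exited"; outlet <- cross$tag
        exit_t <- t + cross$s * dt
        exit_speed <- if (inertial) sqrt(sum(yc[3:4]^2))
                      else attr(dc, "speed")
        path[[length(path) + 1L]] <- c(exit_t, yc[1:2], attr(dc, "F"))
        t <- exit_t
        break
      }
      dt <- dt / 2
      if (dt < 1e-8) { status <- "frozen_at_wall"; break }
      next
    }
    inc5 <- dt * as.vector(Reduce(`+`, Map(`*`, CK$c5, k)))
    inc4 <- dt * as.vector(Reduce(`+`, Map(`*`, CK$c4, k)))
    err <- sqrt(sum((inc5[1:2] - inc4[1:2])^2))
    if (err > tol && dt > 1e-8) {
      dt <- max(1e-8, 0.9 * dt * (tol / max(err, 1e-300))^0.25)
      next
    }
    yn <- y + inc5
    cross <- outlet_crossing(frames, y[1], y[2], yn[1], yn[2])
    if (!is.null(cross)) {
      yc <- y + cross$s * inc5
      tc <- t + cross$s * dt
      dc <- exit_eval(yc[1:2], inc5[1:2], k[[1]])
      status <- "exited"; outlet <- cross$tag
      exit_t <- tc
      exit_speed <- if (inertial) sqrt(sum(yc[3:4]^2))
                    else attr(dc, "speed")
      path[[length(path) + 1L]] <- c(tc, yc[1:2], attr(dc, "F"))
      t <- tc
      break
    }
    t <- t + dt
    y <- yn
    # wall contact at centre distance < Rp
    wp <- wdist(y[1], y[2])
    if (wp[1] < Rp2) {
      if (!slide) {
        d_cur <- deriv(y)
        path[[length(path) + 1L]] <-
          c(t, y[1:2], if (!is.null(d_cur)) attr(d_cur, "F") else 0)
        status <- "frozen_at_wall"
        break
      }
      # excluded volume: push the centre back to one radius from the
      # nearest solid point (iterate for corners)
      for (rep in 1:3) {
        d <- sqrt(wp[1])
        nrm <- if (d > 1e-9) (y[1:2] - wp[2:3]) / d
               else (path[[length(path)]][2:3] - wp[2:3]) /
                 max(sqrt(sum((path[[length(path)]][2:3] - wp[2:3])^2)), 1e-9)
        y[1:2] <- wp[2:3] + (Rp_c + 1e-3) * nrm
        wp <- wdist(y[1], y[2])
        if (wp[1] >= Rp2) break
      }
      if (wp[1] < Rp2 * 0.99) { status <- "frozen_at_wall"; break }
    }
    d_cur <- deriv(y)
    Fmag <- if (!is.null(d_cur)) attr(d_cur, "F") else 0
    path[[length(path) + 1L]] <- c(t, y[1:2], Fmag)
    dt <- min(settings$max_step_s,
              0.9 * dt * (tol / max(err, 1e-300))^0.2)
  }
  pm <- do.call(rbind, path)
  colnames(pm) <- c("t_s", "x_um", "y_um", "F_N")
  list(status = status, outlet = outlet, exit_time_s = exit_t,
       exit_speed_um_s = exit_speed, path = pm)
}

#' @exportS3Method base::print
print.trajectory_set <- function(x, ...) {
  st <- vapply(x, function(t) t$status, character(1))
  cat("<trajectory_set> ", length(x), "particles:",
      paste(names(table(st)), table(st), collapse = ", "), "\n")
  invisible(x)
}

#' Assign terminated trajectories to outlets
#'
#' Maps each particle to the outlet it exited through, or `"lost"` for
#' frozen / unresolved trajectories.
#'
#' @param trajectories An [advance_particles()] result.
#' @param geometry The device geometry (unused beyond validation; the
#'   crossing face is recorded during tracing).
#' @return data.frame of class `outlet_assignment`: `id`, `species`,
#'   `outlet` (tag or `"lost"`), `status`, `exit_time_s`,
#'   `exit_speed_um_s`, plus the species -> target-outlet map as the
#'   `"target_map"` attribute.
#' @export
assign_outlets <- function(trajectories, geometry = NULL) {
  stopifnot(inherits(trajectories, "trajectory_set"))
  df <- do.call(rbind, lapply(trajectories, function(tr) {
    data.frame(id = tr$id, species = tr$species,
               outlet = if (tr$status == "exited") tr$outlet else "lost",
               status = tr$status, exit_time_s = tr$exit_time_s,
               exit_speed_um_s = tr$exit_speed_um_s,
               stringsAsFactors = FALSE)
  }))
  attr(df, "target_map") <- TARGET_OUTLETS
  class(df) <- c("outlet_assignment", "data.frame")
  df
}

#' Integrate pure streamlines of the flow (reference oracle)
#'
#' Independent advection-only integration with `deSolve::lsoda`, used as
#' the reference for the zero-voltage behaviour of the particle tracer.
#'
#' @param flow A [solve_stokes()] result.
#' @param starts n x 2 matrix of seed points, um.
#' @param t_end_s Integration window, s.
#' @param n_out Number of reported time points.
#' @return List of matrices (t, x, y); integration stops early (values
#'   held) where a streamline leaves the domain.
#' @export
streamlines <- function(flow, starts, t_end_s = 8, n_out = 400) {
  if (is.null(dim(starts))) starts <- matrix(starts, ncol = 2)
  fev <- make_field_eval(flow, NULL)
  f <- function(t, y, parms) {
    v <- fev(y[1], y[2])
    if (is.null(v)) return(list(c(0, 0)))
    list(v[1:2])
  }
  lapply(seq_len(nrow(starts)), function(i) {
    times <- seq(0, t_end_s, length.out = n_out)
    o <- deSolve::lsoda(starts[i, ], times, f, NULL,
                        rtol = 1e-10, atol = 1e-8)
    m <- unclass(o)[, 1:3, drop = FALSE]
    colnames(m) <- c("t_s", "x_um", "y_um")
    m
  })
}
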