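# Parametric two-stage Y-channel geometry with protruding electrodes.
#
# Coordinate convention: x along the main channel (flow direction), y across
# it, lengths in um. The main channel occupies y in [0, CW]; the assembled
# polygon is NOT shifted to the bounding-box origin so that the main-channel
# walls stay at y = 0 and y = CW, which keeps the electrode layout and all
# junction constructions readable. The bounding box is reported separately.

S2 <- 1 / sqrt(2)

#' Device parameters of the two-stage Y-channel separator
#'
#' All lengths in um. Defaults are the reference design dimensions
#' (190/500/60/190 um channel lengths, 100 um depth, 16 um electrode
#' protrusion, 40 um electrode width and gap, 90 degree branch angles).
#'
#' @param inlet_length_um,main_channel_length_um,secondary_channel_length_um,outlet_length_um
#'   Channel lengths IL, CL1, CL2, OL.
#' @param channel_width_um Channel width CW (uniform across the network).
#' @param channel_depth_um Channel depth CD; used only to convert 2D flux to
#'   volumetric throughput.
#' @param inlet_angle_deg,outlet_angle_deg Angle between the two branches at
#'   each Y (only the 90 degree layout is implemented; each branch then runs
#'   at 45 degrees to the local channel axis).
#' @param electrode_protrusion_um Protrusion depth PD of each electrode
#'   notch into the channel from the upper wall.
#' @param electrode_width_um,electrode_gap_um Electrode width e and
#'   electrode-to-electrode gap d along the channel.
#' @param n_electrodes Number of electrodes N (2 or 4).
#' @return Object of class `loc_params`.
#' @export
loc_params <- function(inlet_length_um = 190,
                       main_channel_length_um = 500,
                       secondary_channel_length_um = 60,
                       channel_width_um = 40,
                       channel_depth_um = 100,
                       outlet_length_um = 190,
                       inlet_angle_deg = 90,
                       outlet_angle_deg = 90,
                       electrode_protrusion_um = 16,
                       electrode_width_um = 40,
                       electrode_gap_um = 40,
                       n_electrodes = 4) {
  p <- list(inlet_length_um = inlet_length_um,
            main_channel_length_um = main_channel_length_um,
            secondary_channel_length_um = secondary_channel_length_um,
            channel_width_um = channel_width_um,
            channel_depth_um = channel_depth_um,
            outlet_length_um = outlet_length_um,
            inlet_angle_deg = inlet_angle_deg,
            outlet_angle_deg = outlet_angle_deg,
            electrode_protrusion_um = electrode_protrusion_um,
            electrode_width_um = electrode_width_um,
            electrode_gap_um = electrode_gap_um,
            n_electrodes = as.integer(n_electrodes))
  lens <- c("inlet_length_um", "main_channel_length_um",
            "secondary_channel_length_um", "channel_width_um",
            "channel_depth_um", "outlet_length_um", "electrode_width_um",
            "electrode_gap_um")
  for (f in lens)
    if (!is.finite(p[[f]]) || p[[f]] <= 0)
      stop("parameter error: ", f, " must be > 0")
  if (p$electrode_protrusion_um < 0)
    stop("parameter error: electrode_protrusion_um must be >= 0")
  if (p$electrode_protrusion_um >= p$channel_width_um)
    stop("parameter error: electrode_protrusion_um must be smaller than ",
         "channel_width_um")
  if (!p$n_electrodes %in% c(2L, 4L))
    stop("parameter error: n_electrodes must be 2 or 4")
  if (p$n_electrodes * p$electrode_width_um +
      (p$n_electrodes - 1) * p$electrode_gap_um > p$main_channel_length_um)
    stop("parameter error: electrode array (n_electrodes, ",
         "electrode_width_um, electrode_gap_um) does not fit in ",
         "main_channel_length_um")
  if (p$inlet_angle_deg != 90 || p$outlet_angle_deg != 90)
    stop("parameter error: inlet_angle_deg/outlet_angle_deg: only the 90 ",
         "degree branch layout is implemented")
  structure(p, class = "loc_params")
}

shoelace_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  n <- nrow(pts)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Build the tagged planar geometry of the separator
#'
#' Assembles the two-stage Y-channel as a simple polygon with named
#' boundary segments: `blood_inlet` (upper inlet branch), `buffer_inlet`
#' (lower branch), `outlet_PLT` (upper, electrode side), `outlet_CTC`
#' (middle), `outlet_WBC` (lower), `electrode_1..N` (the three exposed
#' faces of each notch) and `wall`.
#'
#' Branch lengths are measured along each branch axis. Each terminal branch
#' includes a fixed junction clearance (inlets: CW/2, i.e. measured from
#' the junction nose; WBC outlet: 5CW/4 from the junction centre; CTC/PLT
#' outlets: 3CW/5 from the second-split centre); these layout constants are
#' fixed once so that the default dimensions at CW = 40 um reproduce the
#' reference 919 um x 440 um device footprint.
#'
#' @param params A [loc_params()].
#' @return Object of class `loc_geometry` with elements `params`,
#'   `vertices` (polygon vertex matrix, um), `edges` (tagged boundary
#'   segments), `area_um2`, `bbox`, `frames` (inlet/outlet face segments
#'   with flow directions) and `layout` (named construction points used by
#'   the mesher).
#' @export
build_loc_geometry <- function(params = loc_params()) {
  if (!inherits(params, "loc_params")) params <- do.call(loc_params, params)
  CW <- params$channel_width_um
  IL <- params$inlet_length_um
  CL1 <- params$main_channel_length_um
  CL2 <- params$secondary_channel_length_um
  OL <- params$outlet_length_um
  PD <- params$electrode_protrusion_um
  ew <- params$electrode_width_um
  eg <- params$electrode_gap_um
  N <- params$n_electrodes

  half <- CW / 2
  jx <- CW * (sqrt(2) - 1) / 2      # wall/junction x-offset
  nose <- CW * S2                    # junction-centre -> nose distance
  r_c <- OL + CW / 10                # CTC/PLT branch length past junction-3 face
  q_b <- OL + 3 * CW / 4             # WBC branch length past junction-2 face

  d_blood <- c(S2, -S2)   # inflow direction of the upper (blood) branch
  d_buffer <- c(S2, S2)   # inflow direction of the lower (buffer) branch
  d_sec <- c(S2, S2)      # secondary-channel axis
  d_wbc <- c(S2, -S2)     # WBC branch axis

  C1 <- c(0, half); C2 <- c(CL1, half); C3 <- C2 + CL2 * d_sec
  W <- c(-nose, half)
  T1 <- c(0, half + nose); T2 <- c(0, half - nose)
  P_up <- c(jx, CW); P_down <- c(jx, 0); M1 <- c(jx, half)
  A1 <- W + IL * c(-S2, S2); A2 <- T1 + IL * c(-S2, S2)
  B1 <- W + IL * c(-S2, -S2); B2 <- T2 + IL * c(-S2, -S2)
  xJ2 <- CL1 - jx
  W2 <- c(CL1 + nose, half)
  T1p <- c(CL1, half + nose); T2p <- c(CL1, half - nose)
  Pp_up <- c(xJ2, CW); Pp_down <- c(xJ2, 0); M2 <- c(xJ2, half)
  Q1 <- C3 + c(-half, jx); Q2 <- C3 + c(jx, -half)
  F1 <- C3 + c(-half, half); F2 <- C3 + c(half, -half)
  N3 <- C3 + c(half, half)
  CT1 <- C3 + c(half + r_c, half); CT2 <- C3 + c(half + r_c, -half)
  PL1 <- C3 + c(-half, half + r_c); PL2 <- C3 + c(half, half + r_c)
  WB1 <- W2 + q_b * d_wbc; WB2 <- T2p + q_b * d_wbc

  # electrode notches on the upper wall, array ending at the first split
  el_right <- xJ2 - (N - seq_len(N)) * (ew + eg)
  el_left <- el_right - ew
  if (el_left[1] <= jx)
    stop("parameter error: electrode array does not fit between the ",
         "junctions of the main channel")

  pts <- list(); tags <- character(0)
  add <- function(p, tag) {
    pts[[length(pts) + 1L]] <<- p
    tags[length(tags) + 1L] <<- tag  # tag of the edge LEAVING this point
  }
  add(A1, "blood_inlet"); add(A2, "wall")           # inlet face, outer wall
  add(P_up, "wall")                                  # begin upper wall
  for (k in seq_len(N)) {
    add(c(el_left[k], CW), paste0("electrode_", k))
    add(c(el_left[k], CW - PD), paste0("electrode_", k))
    add(c(el_right[k], CW - PD), paste0("electrode_", k))
    if (el_right[k] < xJ2 - 1e-9) add(c(el_right[k], CW), "wall")
  }
  add(Pp_up, "wall")
  add(Q1, "wall")                                    # PLT-branch left wall
  add(PL1, "outlet_PLT")
  add(PL2, "wall")                                   # PLT right wall down
  add(N3, "wall")                                    # CTC upper wall
  add(CT1, "outlet_CTC")
  add(CT2, "wall")                                   # CTC lower wall back
  add(Q2, "wall")                                    # secondary lower wall
  add(W2, "wall")                                    # WBC inner wall
  add(WB1, "outlet_WBC")
  add(WB2, "wall")                                   # WBC outer wall back
  add(Pp_down, "wall")                               # bottom channel wall
  add(P_down, "wall")                                # buffer outer wall
  add(B2, "buffer_inlet")
  add(B1, "wall")                                    # buffer inner wall
  add(W, "wall")                                     # blood inner wall
  V <- do.call(rbind, pts)
  nV <- nrow(V)
  edges <- data.frame(x1 = V[, 1], y1 = V[, 2],
                      x2 = V[c(2:nV, 1), 1], y2 = V[c(2:nV, 1), 2],
                      tag = tags, stringsAsFactors = FALSE)

  frames <- list(
    blood_inlet = list(p1 = A1, p2 = A2, dir = d_blood),
    buffer_inlet = list(p1 = B2, p2 = B1, dir = d_buffer),
    outlet_WBC = list(p1 = WB1, p2 = WB2, dir = d_wbc),
    outlet_CTC = list(p1 = CT1, p2 = CT2, dir = c(1, 0)),
    outlet_PLT = list(p1 = PL1, p2 = PL2, dir = c(0, 1)))

  layout <- list(C1 = C1, C2 = C2, C3 = C3, W = W, T1 = T1, T2 = T2,
                 P_up = P_up, P_down = P_down, M1 = M1,
                 W2 = W2, T1p = T1p, T2p = T2p, Pp_up = Pp_up,
                 Pp_down = Pp_down, M2 = M2,
                 Q1 = Q1, Q2 = Q2, F1 = F1, F2 = F2, N3 = N3,
                 CT1 = CT1, CT2 = CT2, PL1 = PL1, PL2 = PL2,
                 WB1 = WB1, WB2 = WB2, A1 = A1, A2 = A2, B1 = B1, B2 = B2,
                 el_left = el_left, el_right = el_right,
                 xJ1 = jx, xJ2 = xJ2)

  structure(list(type = "loc", params = params, vertices = V, edges = edges,
                 area_um2 = shoelace_area(V),
                 bbox = c(xmin = min(V[, 1]), xmax = max(V[, 1]),
                          ymin = min(V[, 2]), ymax = max(V[, 2])),
                 frames = frames, layout = layout),
            class = "loc_geometry")
}

#' @exportS3Method base::print
print.loc_geometry <- function(x, ...) {
  bb <- x$bbox
  cat(sprintf("<loc_geometry %s>  bbox %.1f x %.1f um, area %.0f um^2, %d boundary segments\n",
              x$type, bb["xmax"] - bb["xmin"], bb["ymax"] - bb["ymin"],
              x$area_um2, nrow(x$edges)))
  invisible(x)
}

#' Rectangular channel fixture geometry
#'
#' A plain rectangle `[0, length] x [0, width]` with one tag per side, used
#' for analytic verification cases (plane Poiseuille flow, parallel-plate
#' fields).
#'
#' @param length_um,width_um Rectangle dimensions, um.
#' @param tags Named character vector with entries `left`, `right`, `top`,
#'   `bottom` giving the boundary tag of each side.
#' @param depth_um Out-of-plane depth (throughput conversion only).
#' @return Object of class `loc_geometry` (type `"rect"`).
#' @export
rect_channel_geometry <- function(length_um, width_um,
                                  tags = c(left = "blood_inlet",
                                           right = "outlet_CTC",
                                           top = "wall", bottom = "wall"),
                                  depth_um = 100) {
  stopifnot(length_um > 0, width_um > 0,
            all(c("left", "right", "top", "bottom") %in% names(tags)))
  V <- rbind(c(0, 0), c(length_um, 0), c(length_um, width_um), c(0, width_um))
  edges <- data.frame(
    x1 = V[, 1], y1 = V[, 2],
    x2 = V[c(2, 3, 4, 1), 1], y2 = V[c(2, 3, 4, 1), 2],
    tag = unname(tags[c("bottom", "right", "top", "left")]),
    stringsAsFactors = FALSE)
  frames <- list()
  frames[[tags[["left"]]]] <- list(p1 = c(0, 0), p2 = c(0, width_um),
                                   dir = c(1, 0))
  frames[[tags[["right"]]]] <- list(p1 = c(length_um, 0),
                                    p2 = c(length_um, width_um),
                                    dir = c(1, 0))
  structure(list(type = "rect", params = list(length_um = length_um,
                                              width_um = width_um,
                                              channel_depth_um = depth_um),
                 vertices = V, edges = edges,
                 area_um2 = length_um * width_um,
                 bbox = c(xmin = 0, xmax = length_um,
                          ymin = 0, ymax = width_um),
                 frames = frames, layout = NULL),
            class = "loc_geometry")
}

# even-odd ray casting; pts n x 2, polygon vertex matrix (open)
point_in_polygon <- function(pts, poly) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  n <- nrow(poly)
  jj <- c(n, seq_len(n - 1))
  inside <- rep(FALSE, nrow(pts))
  for (k in seq_len(n)) {
    xi <- poly[k, 1]; yi <- poly[k, 2]
    xj <- poly[jj[k], 1]; yj <- poly[jj[k], 2]
    cross <- ((yi > pts[, 2]) != (yj > pts[, 2])) &
      (pts[, 1] < (xj - xi) * (pts[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
  }
  inside
}

# do any two non-adjacent polygon edges intersect? (simplicity check)
polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  seg_int <- function(p1, p2, p3, p4) {
    d1 <- p2 - p1; d2 <- p4 - p3
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-12) return(FALSE)
    t <- ((p3[1] - p1[1]) * d2[2] - (p3[2] - p1[2]) * d2[1]) / den
    u <- ((p3[1] - p1[1]) * d1[2] - (p3[2] - p1[2]) * d1[1]) / den
    t > 1e-9 && t < 1 - 1e-9 && u > 1e-9 && u < 1 - 1e-9
  }
  idx <- cbind(seq_len(n), c(2:n, 1))
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      if (abs(a - b) <= 1 || (a == 1 && b == n)) next
      if (seg_int(poly[idx[a, 1], ], poly[idx[a, 2], ],
                  poly[idx[b, 1], ], poly[idx[b, 2], ])) return(FALSE)
    }
  }
  TRUE
}

#' Echo a geometry as JSON
#'
#' @param geometry A [build_loc_geometry()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_geometry_json <- function(geometry, path) {
  out <- list(type = geometry$type,
              params = unclass(geometry$params),
              bbox = as.list(geometry$bbox),
              area_um2 = geometry$area_um2,
              vertices = geometry$vertices,
              edges = geometry$edges)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
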