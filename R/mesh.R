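# Block-structured triangular meshing of the channel network.
#
# Every region of the device is a mapped quadrilateral patch (Coons patch
# with independently parameterized straight edges); the three Y-junction
# pentagons are subdivided midpoint-wise into five quads so that every
# boundary half-edge faces an interior edge and patch interfaces conform
# exactly. Quads are split into positively oriented triangles and nodes
# merged across patches by coordinate.

MESH_LEVELS <- c(coarse = 8, normal = 4, fine = 2)  # target h, um

new_mesh_collector <- function() {
  env <- new.env(parent = emptyenv())
  env$nodes <- list(); env$tris <- list()
  env
}

# transfinite quad patch; corners c1..c4 CCW, f* = edge break fractions
# (0..1 inclusive): f12 along c1->c2, f43 along c4->c3 (same length), f14
# along c1->c4, f23 along c2->c3 (same length)
collect_quad_patch <- function(env, c1, c2, c3, c4, f12, f43, f14, f23) {
  stopifnot(length(f12) == length(f43), length(f14) == length(f23))
  nu <- length(f12); nv <- length(f14)
  u <- seq(0, 1, length.out = nu); v <- seq(0, 1, length.out = nv)
  E12x <- c1[1] + f12 * (c2[1] - c1[1]); E12y <- c1[2] + f12 * (c2[2] - c1[2])
  E43x <- c4[1] + f43 * (c3[1] - c4[1]); E43y <- c4[2] + f43 * (c3[2] - c4[2])
  E14x <- c1[1] + f14 * (c4[1] - c1[1]); E14y <- c1[2] + f14 * (c4[2] - c1[2])
  E23x <- c2[1] + f23 * (c3[1] - c2[1]); E23y <- c2[2] + f23 * (c3[2] - c2[2])
  U <- matrix(u, nu, nv); V <- matrix(v, nu, nv, byrow = TRUE)
  X <- (1 - V) * E12x + V * E43x + (1 - U) * matrix(E14x, nu, nv, byrow = TRUE) +
    U * matrix(E23x, nu, nv, byrow = TRUE) -
    ((1 - U) * (1 - V) * c1[1] + U * (1 - V) * c2[1] + U * V * c3[1] +
       (1 - U) * V * c4[1])
  Y <- (1 - V) * E12y + V * E43y + (1 - U) * matrix(E14y, nu, nv, byrow = TRUE) +
    U * matrix(E23y, nu, nv, byrow = TRUE) -
    ((1 - U) * (1 - V) * c1[2] + U * (1 - V) * c2[2] + U * V * c3[2] +
       (1 - U) * V * c4[2])
  collect_grid(env, X, Y)
}

# structured grid of nodes (nu x nv matrices of coordinates) -> triangles
collect_grid <- function(env, X, Y) {
  nu <- nrow(X); nv <- ncol(X)
  base <- sum(vapply(env$nodes, nrow, 1L))
  idx <- matrix(seq_len(nu * nv) + base, nu, nv)
  env$nodes[[length(env$nodes) + 1L]] <- cbind(as.vector(X), as.vector(Y))
  i <- rep(seq_len(nu - 1), nv - 1)
  j <- rep(seq_len(nv - 1), each = nu - 1)
  n1 <- idx[cbind(i, j)]; n2 <- idx[cbind(i + 1, j)]
  n3 <- idx[cbind(i + 1, j + 1)]; n4 <- idx[cbind(i, j + 1)]
  env$tris[[length(env$tris) + 1L]] <-
    rbind(cbind(n1, n2, n3), cbind(n1, n3, n4))
  invisible(env)
}

# pentagon (CCW vertex list) -> 5 quads about the centroid; ebreaks[[k]] =
# fraction vector of edge p_k -> p_{k+1}, each containing 0.5
collect_pentagon <- function(env, pts, ebreaks) {
  n <- nrow(pts)
  O <- colMeans(pts)
  nxt <- c(2:n, 1); prv <- c(n, 1:(n - 1))
  mids <- (pts + pts[nxt, ]) / 2
  halves <- lapply(seq_len(n), function(k) {
    f <- ebreaks[[k]]
    if (!any(abs(f - 0.5) < 1e-9))
      stop("pentagon edge breaks must contain the midpoint")
    list(lo = f[f <= 0.5 + 1e-9] / 0.5,
         hi = (f[f >= 0.5 - 1e-9] - 0.5) / 0.5)
  })
  for (k in seq_len(n)) {
    kp <- prv[k]
    # quad: m_{k-1,k} -> p_k -> m_{k,k+1} -> O
    f12 <- halves[[kp]]$hi                 # m_prev -> p_k
    f23 <- halves[[k]]$lo                  # p_k -> m_k
    f43 <- seq(0, 1, length.out = length(f12))  # O -> m_k? (interior)
    f14 <- seq(0, 1, length.out = length(f23))
    collect_quad_patch(env, mids[kp, ], pts[k, ], mids[k, ], O,
                       f12, f43, f14, f23)
  }
  invisible(env)
}

# main-channel block with electrode notches: columns between x-breaks,
# global y-breaks, per-column top at CW or CW - PD inside a notch
collect_channel_block <- function(env, xb, yb, CW, PD, el_left, el_right) {
  for (i in seq_len(length(xb) - 1)) {
    xm <- (xb[i] + xb[i + 1]) / 2
    in_notch <- PD > 0 && any(xm > el_left & xm < el_right)
    top <- if (in_notch) CW - PD else CW
    yy <- yb[yb <= top + 1e-9]
    X <- matrix(rep(c(xb[i], xb[i + 1]), each = length(yy)), ncol = 2)
    Y <- matrix(rep(yy, 2), ncol = 2)
    collect_grid(env, t(X), t(Y))
  }
  invisible(env)
}

# one conforming red-green refinement pass: triangles in `mark` are
# red-refined (1 -> 4); neighbours are promoted or green-bisected so no
# hanging nodes remain
refine_marked <- function(nodes, tris, mark) {
  nv <- nrow(nodes); m <- nrow(tris)
  pair_key <- function(a, b) pmin(a, b) + pmax(a, b) * (nv + 1)
  tek <- cbind(pair_key(tris[, 1], tris[, 2]),
               pair_key(tris[, 2], tris[, 3]),
               pair_key(tris[, 3], tris[, 1]))
  uk <- unique(as.vector(tek))
  eidx <- matrix(match(as.vector(tek), uk), m, 3)
  split <- logical(length(uk))
  split[as.vector(eidx[mark, ])] <- TRUE
  repeat {
    cnt <- rowSums(matrix(split[eidx], m, 3))
    promote <- cnt == 2
    if (!any(promote)) break
    split[as.vector(eidx[promote, ])] <- TRUE
  }
  # midpoint node for each split edge (decode key = lo + hi*(nv+1))
  se <- which(split)
  hi <- uk[se] %/% (nv + 1)
  lo <- uk[se] - hi * (nv + 1)
  mid_id <- integer(length(uk))
  mid_id[se] <- nv + seq_along(se)
  nodes2 <- rbind(nodes, (nodes[lo, , drop = FALSE] +
                            nodes[hi, , drop = FALSE]) / 2)
  out <- vector("list", m)
  cnt <- rowSums(matrix(split[eidx], m, 3))
  for (t in seq_len(m)) {
    v <- tris[t, ]
    s <- split[eidx[t, ]]
    if (cnt[t] == 0) { out[[t]] <- matrix(v, 1, 3); next }
    mm <- mid_id[eidx[t, ]]
    if (cnt[t] == 3) {
      out[[t]] <- rbind(c(v[1], mm[1], mm[3]), c(mm[1], v[2], mm[2]),
                        c(mm[3], mm[2], v[3]), c(mm[1], mm[2], mm[3]))
    } else {  # exactly one split edge: green bisection
      i <- which(s)
      a <- v[i]; b <- v[i %% 3 + 1]; c0 <- v[(i + 1) %% 3 + 1]
      out[[t]] <- rbind(c(a, mm[i], c0), c(mm[i], b, c0))
    }
  }
  list(nodes = nodes2, tris = do.call(rbind, out))
}

# cascaded local refinement around segments (electrode faces): one pass
# per radius, largest first
refine_near_segments <- function(nodes, tris, segs, radii) {
  for (r in radii) {
    cx <- (nodes[tris[, 1], 1] + nodes[tris[, 2], 1] + nodes[tris[, 3], 1]) / 3
    cy <- (nodes[tris[, 1], 2] + nodes[tris[, 2], 2] + nodes[tris[, 3], 2]) / 3
    near <- rep(FALSE, nrow(tris))
    for (s in seq_len(nrow(segs))) {
      dxs <- segs[s, 3] - segs[s, 1]; dys <- segs[s, 4] - segs[s, 2]
      L2 <- dxs^2 + dys^2
      tt <- pmin(1, pmax(0, ((cx - segs[s, 1]) * dxs +
                               (cy - segs[s, 2]) * dys) / L2))
      d2 <- (cx - (segs[s, 1] + tt * dxs))^2 +
        (cy - (segs[s, 2] + tt * dys))^2
      near <- near | d2 < r^2
    }
    if (!any(near)) next
    rr <- refine_marked(nodes, tris, which(near))
    nodes <- rr$nodes; tris <- rr$tris
  }
  list(nodes = nodes, tris = tris)
}

dedupe_nodes <- function(nodes, tris, tol = 1e-6) {
  key <- paste(round(nodes[, 1] / tol) * tol, round(nodes[, 2] / tol) * tol)
  first <- !duplicated(key)
  map <- match(key, key[first])
  new_nodes <- nodes[first, , drop = FALSE]
  new_tris <- matrix(map[tris], ncol = 3)
  list(nodes = new_nodes, tris = new_tris)
}

triangle_areas <- function(nodes, tris) {
  p1 <- nodes[tris[, 1], , drop = FALSE]
  p2 <- nodes[tris[, 2], , drop = FALSE]
  p3 <- nodes[tris[, 3], , drop = FALSE]
  ((p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
      (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])) / 2
}

# graded breakpoints: uniform by h plus mandatory refinement clusters
# around `at` (the cluster points are kept exactly; uniform points too
# close to a cluster are dropped instead)
refined_breaks <- function(from, to, h, at = numeric(0), ref = h / 4) {
  manda <- as.vector(outer(at, c(0, -ref, ref, -2 * ref, 2 * ref), "+"))
  manda <- manda[manda > from + 1e-9 & manda < to - 1e-9]
  n <- max(1L, round((to - from) / h))
  unif <- seq(from, to, length.out = n + 1)
  if (length(manda)) {
    drop <- vapply(unif, function(x) any(abs(x - manda) < ref * 0.999),
                   logical(1))
    drop[c(1, length(unif))] <- FALSE
    unif <- unif[!drop]
  }
  sort(unique(round(c(unif, manda), 7)))
}

frac <- function(b) (b - b[1]) / (b[length(b)] - b[1])

# grid on [0, W] with 2*nh intervals, containing W/2 and (optionally) one
# special line `sp`, each sub-range filled uniformly
split_uniform <- function(W, nh, sp = NULL) {
  lower <- seq(0, W / 2, length.out = nh + 1)
  upper <- seq(W / 2, W, length.out = nh + 1)
  place <- function(a, b, s, n) {
    # n intervals on [a, b] containing s strictly inside
    k <- max(1L, min(n - 1L, round(n * (s - a) / (b - a))))
    c(seq(a, s, length.out = k + 1), seq(s, b, length.out = n - k + 1)[-1])
  }
  if (!is.null(sp) && abs(sp - W / 2) > 1e-9 && sp > 1e-9 && sp < W - 1e-9) {
    if (sp > W / 2) upper <- place(W / 2, W, sp, nh)
    else lower <- place(0, W / 2, sp, nh)
  }
  round(c(lower, upper[-1]), 9)
}

even_breaks <- function(len, h) {
  n <- max(2L, 2L * ceiling(len / (2 * h)))
  seq(0, 1, length.out = n + 1)
}

#' Generate a tagged triangular mesh of a device geometry
#'
#' Builds a conforming all-triangle mesh of the channel network at one of
#' three refinement levels (characteristic element size 8, 4 and 2 um for
#' coarse, normal and fine; the size halves per level) with 4x local
#' refinement around the electrode notch corners, where the gradient of
#' |E|^2 that drives the DEP force is strongest.
#'
#' @param geometry A [build_loc_geometry()] or [rect_channel_geometry()].
#' @param level `"coarse"`, `"normal"` or `"fine"`.
#' @param h_um Optional explicit characteristic element size overriding
#'   `level`.
#' @return Object of class `loc_mesh`: `nodes` (n x 2, um), `tri`
#'   (m x 3, positively oriented), `boundary` (tagged boundary edges),
#'   `areas_um2`, `level`, `h_um`, and the generating `geometry`.
#' @export
generate_mesh <- function(geometry, level = c("normal", "coarse", "fine"),
                          h_um = NULL) {
  stopifnot(inherits(geometry, "loc_geometry"))
  level <- match.arg(level)
  h <- if (is.null(h_um)) MESH_LEVELS[[level]] else h_um
  env <- new_mesh_collector()

  if (geometry$type == "rect") {
    L <- geometry$params$length_um; Wd <- geometry$params$width_um
    fx <- even_breaks(L, h); fy <- even_breaks(Wd, h)
    collect_quad_patch(env, c(0, 0), c(L, 0), c(L, Wd), c(0, Wd),
                       fx, fx, fy, fy)
  } else {
    P <- geometry$params; ly <- geometry$layout
    CW <- P$channel_width_um; PD <- P$electrode_protrusion_um
    nw <- max(4L, 2L * ceiling(CW / (2 * h)))
    ws <- seq(0, 1, length.out = nw + 1)                  # width fractions
    # channel-block y breaks: near-uniform grid of nw intervals containing
    # both the channel mid-line and the notch-depth line CW - PD (the
    # junction pentagons require one common break count on all their edges)
    yb <- split_uniform(CW, nw %/% 2, if (PD > 0) CW - PD else NULL)
    xb <- refined_breaks(ly$xJ1, ly$xJ2, h,
                         at = c(ly$el_left, ly$el_right), ref = h / 4)
    collect_channel_block(env, xb, yb, CW, PD, ly$el_left, ly$el_right)

    ax <- function(len) even_breaks(len, h)   # axial break fractions
    IL <- P$inlet_length_um
    # inlet branches (u along axis towards the junction, v across width)
    collect_quad_patch(env, ly$A1, ly$W, ly$T1, ly$A2,
                       ax(IL), ax(IL), ws, ws)
    collect_quad_patch(env, ly$B2, ly$T2, ly$W, ly$B1,
                       ax(IL), ax(IL), ws, ws)
    # secondary channel
    l2 <- sqrt(sum((ly$Q2 - ly$W2)^2))
    collect_quad_patch(env, ly$W2, ly$Q2, ly$Q1, ly$T1p,
                       ax(l2), ax(l2), ws, ws)
    # outlet branches
    lw <- sqrt(sum((ly$WB2 - ly$T2p)^2))
    collect_quad_patch(env, ly$T2p, ly$WB2, ly$WB1, ly$W2,
                       ax(lw), ax(lw), ws, ws)
    lc <- sqrt(sum((ly$CT1 - ly$N3)^2))
    collect_quad_patch(env, ly$F2, ly$CT2, ly$CT1, ly$N3,
                       ax(lc), ax(lc), ws, ws)
    lp <- sqrt(sum((ly$PL2 - ly$N3)^2))
    collect_quad_patch(env, ly$N3, ly$PL2, ly$PL1, ly$F1,
                       ax(lp), ax(lp), ws, ws)
    # junction pentagons (CCW; all edges share one break count and
    # contain the midpoint)
    wall5 <- function(p, q) seq(0, 1, length.out = nw + 1)
    yb_f <- frac(yb)
    collect_pentagon(env, rbind(ly$W, ly$T2, ly$P_down, ly$P_up, ly$T1),
                     list(ws,                      # W -> T2 buffer face
                          wall5(ly$T2, ly$P_down), # wall
                          yb_f,                    # channel interface
                          wall5(ly$P_up, ly$T1),   # wall
                          ws))                     # blood face T1 -> W
    collect_pentagon(env, rbind(ly$Pp_down, ly$T2p, ly$W2, ly$T1p, ly$Pp_up),
                     list(wall5(ly$Pp_down, ly$T2p),
                          ws,                      # WBC face
                          ws,                      # secondary face
                          wall5(ly$T1p, ly$Pp_up),
                          rev(1 - yb_f)))          # channel interface (descending)
    collect_pentagon(env, rbind(ly$Q1, ly$Q2, ly$F2, ly$N3, ly$F1),
                     list(ws,                      # incoming secondary face
                          wall5(ly$Q2, ly$F2),
                          ws,                      # CTC face
                          ws,                      # PLT face
                          wall5(ly$F1, ly$Q1)))
  }

  nodes <- do.call(rbind, env$nodes)
  tris <- do.call(rbind, env$tris)
  dd <- dedupe_nodes(nodes, tris)
  nodes <- dd$nodes; tris <- dd$tris
  # graded local refinement around the electrode faces, where the
  # grad|E|^2 singularities drive the DEP force
  if (geometry$type == "loc" && geometry$params$electrode_protrusion_um > 0) {
    P <- geometry$params; ly <- geometry$layout
    segs <- cbind(ly$el_left, P$channel_width_um - P$electrode_protrusion_um,
                  ly$el_right, P$channel_width_um - P$electrode_protrusion_um)
    rr <- refine_near_segments(nodes, tris, segs, c(6, 3, 1.5))
    nodes <- rr$nodes; tris <- rr$tris
  }
  # enforce positive orientation, drop degenerate slivers
  ar <- triangle_areas(nodes, tris)
  flip <- ar < 0
  tris[flip, c(2, 3)] <- tris[flip, c(3, 2)]
  ar <- abs(ar)
  keep <- ar > 1e-9
  tris <- tris[keep, , drop = FALSE]; ar <- ar[keep]

  bnd <- extract_boundary(nodes, tris, geometry)
  rel_gap <- abs(sum(ar) - geometry$area_um2) / geometry$area_um2
  if (rel_gap > 1e-6)
    stop("geometry error: mesh area does not match the polygon area ",
         "(relative gap ", format(rel_gap), ")")
  structure(list(nodes = nodes, tri = tris, boundary = bnd,
                 areas_um2 = ar, level = level, h_um = h,
                 geometry = geometry),
            class = "loc_mesh")
}

#' @exportS3Method base::print
print.loc_mesh <- function(x, ...) {
  cat(sprintf("<loc_mesh %s h=%g um>  %d nodes, %d triangles, %d boundary edges\n",
              x$level, x$h_um, nrow(x$nodes), nrow(x$tri), nrow(x$boundary)))
  invisible(x)
}

# boundary edges = edges owned by exactly one triangle; tag each by the
# geometry segment it lies on (errors out on an untaggable edge, which
# would indicate a non-conforming patch interface)
extract_boundary <- function(nodes, tris, geometry) {
  e <- rbind(tris[, c(1, 2)], tris[, c(2, 3)], tris[, c(3, 1)])
  lo <- pmin(e[, 1], e[, 2]); hi <- pmax(e[, 1], e[, 2])
  key <- paste(lo, hi)
  cnt <- table(key)
  b <- key %in% names(cnt)[cnt == 1L]
  be <- unique(cbind(lo, hi)[b, , drop = FALSE])
  mid <- (nodes[be[, 1], , drop = FALSE] + nodes[be[, 2], , drop = FALSE]) / 2
  seg <- geometry$edges
  tag <- rep(NA_character_, nrow(be))
  for (s in seq_len(nrow(seg))) {
    p1 <- c(seg$x1[s], seg$y1[s]); p2 <- c(seg$x2[s], seg$y2[s])
    d <- p2 - p1; len2 <- sum(d^2)
    t <- ((mid[, 1] - p1[1]) * d[1] + (mid[, 2] - p1[2]) * d[2]) / len2
    px <- p1[1] + t * d[1]; py <- p1[2] + t * d[2]
    dist <- sqrt((mid[, 1] - px)^2 + (mid[, 2] - py)^2)
    hit <- is.na(tag) & t >= -1e-9 & t <= 1 + 1e-9 & dist < 1e-5
    tag[hit] <- seg$tag[s]
  }
  if (anyNA(tag)) {
    i <- which(is.na(tag))[1]
    stop("geometry error: untagged boundary edge near (",
         round(mid[i, 1], 3), ", ", round(mid[i, 2], 3), ")")
  }
  data.frame(n1 = be[, 1], n2 = be[, 2], tag = tag,
             stringsAsFactors = FALSE)
}
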