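# P2/P1 finite-element machinery on the triangular meshes.
#
# Scalar fields (potential, velocity components) are quadratic (P2: vertex
# + edge-midpoint dofs); pressure is linear (P1), giving the inf-sup stable
# Taylor-Hood pair for the Stokes system. All assembly is vectorized over
# elements; coordinates are in um throughout (the um/Pa/um-per-s unit
# system keeps the Stokes saddle system free of explicit scale factors).

# degree-5, 7-point symmetric quadrature rule (barycentric, weights sum 1)
TRI_QUAD <- local({
  a1 <- 0.059715871789770; b1 <- 0.470142064105115
  a2 <- 0.797426985353087; b2 <- 0.101286507323456
  lam <- rbind(c(1/3, 1/3, 1/3),
               c(a1, b1, b1), c(b1, a1, b1), c(b1, b1, a1),
               c(a2, b2, b2), c(b2, a2, b2), c(b2, b2, a2))
  w <- c(0.225, rep(0.132394152788506, 3), rep(0.125939180544827, 3))
  list(lam = lam, w = w)
})

# P2 basis values at barycentric coords (rows of lam); dof order:
# vertices 1..3, then midpoints of edges (1,2), (2,3), (3,1)
p2_basis <- function(lam) {
  l1 <- lam[, 1]; l2 <- lam[, 2]; l3 <- lam[, 3]
  cbind(l1 * (2 * l1 - 1), l2 * (2 * l2 - 1), l3 * (2 * l3 - 1),
        4 * l1 * l2, 4 * l2 * l3, 4 * l3 * l1)
}

# coefficients c[a, i] with grad N_a = sum_i c[a, i] * grad lambda_i,
# evaluated at one barycentric point
p2_grad_coef <- function(l) {
  rbind(c(4 * l[1] - 1, 0, 0),
        c(0, 4 * l[2] - 1, 0),
        c(0, 0, 4 * l[3] - 1),
        c(4 * l[2], 4 * l[1], 0),
        c(0, 4 * l[3], 4 * l[2]),
        c(4 * l[3], 0, 4 * l[1]))
}

# global edge numbering and P2 dof map
p2_structure <- function(mesh) {
  tri <- mesh$tri
  m <- nrow(tri); nv <- nrow(mesh$nodes)
  pairs <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  lo <- pmin(pairs[, 1], pairs[, 2]); hi <- pmax(pairs[, 1], pairs[, 2])
  key <- lo + hi * (nv + 1)
  uk <- unique(key)
  eidx <- match(key, uk)
  edges <- cbind(lo, hi)[!duplicated(key), , drop = FALSE]
  tri_dofs <- cbind(tri, matrix(nv + eidx, m, 3))
  mid <- (mesh$nodes[edges[, 1], , drop = FALSE] +
            mesh$nodes[edges[, 2], , drop = FALSE]) / 2
  list(edges = edges, tri_dofs = tri_dofs, n_vertex = nv,
       n_dof = nv + nrow(edges),
       dof_coords = rbind(mesh$nodes, mid),
       edge_key = uk)
}

# per-element geometry: grad lambda_i (constant per element) and areas
tri_geometry <- function(mesh) {
  p1 <- mesh$nodes[mesh$tri[, 1], , drop = FALSE]
  p2 <- mesh$nodes[mesh$tri[, 2], , drop = FALSE]
  p3 <- mesh$nodes[mesh$tri[, 3], , drop = FALSE]
  A2 <- (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
    (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])   # 2*area, > 0
  gx <- cbind(p2[, 2] - p3[, 2], p3[, 2] - p1[, 2], p1[, 2] - p2[, 2]) / A2
  gy <- cbind(p3[, 1] - p2[, 1], p1[, 1] - p3[, 1], p2[, 1] - p1[, 1]) / A2
  list(gx = gx, gy = gy, area = A2 / 2)
}

# P2 scalar stiffness integral(grad u . grad v); sparse n_dof x n_dof
assemble_p2_stiffness <- function(mesh, st, geom = tri_geometry(mesh)) {
  m <- nrow(mesh$tri)
  q <- TRI_QUAD
  Ke <- matrix(0, m, 36)
  for (k in seq_along(q$w)) {
    C <- p2_grad_coef(q$lam[k, ])
    dNx <- geom$gx %*% t(C)   # m x 6
    dNy <- geom$gy %*% t(C)
    wk <- q$w[k] * geom$area
    for (a in 1:6) for (b in 1:6) {
      Ke[, (a - 1) * 6 + b] <- Ke[, (a - 1) * 6 + b] +
        wk * (dNx[, a] * dNx[, b] + dNy[, a] * dNy[, b])
    }
  }
  ii <- rep(st$tri_dofs, times = 6)
  jj <- as.vector(st$tri_dofs[, rep(1:6, each = 6)])
  Matrix::sparseMatrix(i = ii, j = jj, x = as.vector(Ke),
                       dims = c(st$n_dof, st$n_dof))
}

# P1-pressure / P2-velocity divergence blocks D1, D2 with
# D1[p, a] = integral(lambda_p dN_a/dx)
assemble_divergence <- function(mesh, st, geom = tri_geometry(mesh)) {
  m <- nrow(mesh$tri)
  q <- TRI_QUAD
  D1e <- matrix(0, m, 18); D2e <- matrix(0, m, 18)
  for (k in seq_along(q$w)) {
    l <- q$lam[k, ]
    C <- p2_grad_coef(l)
    dNx <- geom$gx %*% t(C)
    dNy <- geom$gy %*% t(C)
    wk <- q$w[k] * geom$area
    for (p in 1:3) for (a in 1:6) {
      col <- (p - 1) * 6 + a
      D1e[, col] <- D1e[, col] + wk * l[p] * dNx[, a]
      D2e[, col] <- D2e[, col] + wk * l[p] * dNy[, a]
    }
  }
  ii <- as.vector(mesh$tri[, rep(1:3, each = 6)])
  jj <- rep(st$tri_dofs, times = 3)
  nv <- st$n_vertex
  list(D1 = Matrix::sparseMatrix(i = ii, j = jj, x = as.vector(D1e),
                                 dims = c(nv, st$n_dof)),
       D2 = Matrix::sparseMatrix(i = ii, j = jj, x = as.vector(D2e),
                                 dims = c(nv, st$n_dof)))
}

# P2 dofs lying on boundary edges with the given tags, with the fractional
# position of each dof along its (first matching) boundary face
boundary_p2_dofs <- function(mesh, st, tags) {
  b <- mesh$boundary[mesh$boundary$tag %in% tags, , drop = FALSE]
  if (nrow(b) == 0) return(integer(0))
  nv <- st$n_vertex
  key <- pmin(b$n1, b$n2) + pmax(b$n1, b$n2) * (nv + 1)
  eidx <- match(key, st$edge_key)
  unique(c(b$n1, b$n2, nv + eidx))
}

# uniform-grid point locator over triangle bounding boxes
build_locator <- function(mesh) {
  bb <- mesh$geometry$bbox
  cs <- max(2 * mesh$h_um, 1)
  nx <- max(1L, ceiling((bb["xmax"] - bb["xmin"]) / cs))
  ny <- max(1L, ceiling((bb["ymax"] - bb["ymin"]) / cs))
  p1 <- mesh$nodes[mesh$tri[, 1], , drop = FALSE]
  p2 <- mesh$nodes[mesh$tri[, 2], , drop = FALSE]
  p3 <- mesh$nodes[mesh$tri[, 3], , drop = FALSE]
  txmin <- pmin(p1[, 1], p2[, 1], p3[, 1]); txmax <- pmax(p1[, 1], p2[, 1], p3[, 1])
  tymin <- pmin(p1[, 2], p2[, 2], p3[, 2]); tymax <- pmax(p1[, 2], p2[, 2], p3[, 2])
  ix1 <- pmax(1L, pmin(nx, floor((txmin - bb["xmin"]) / cs) + 1L))
  ix2 <- pmax(1L, pmin(nx, floor((txmax - bb["xmin"]) / cs) + 1L))
  iy1 <- pmax(1L, pmin(ny, floor((tymin - bb["ymin"]) / cs) + 1L))
  iy2 <- pmax(1L, pmin(ny, floor((tymax - bb["ymin"]) / cs) + 1L))
  cells <- vector("list", nx * ny)
  for (t in seq_len(nrow(mesh$tri))) {
    for (ix in ix1[t]:ix2[t]) for (iy in iy1[t]:iy2[t]) {
      c0 <- (iy - 1L) * nx + ix
      cells[[c0]] <- c(cells[[c0]], t)
    }
  }
  # barycentric transform: lam2 = b11 dx + b12 dy, lam3 = b21 dx + b22 dy
  det <- (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
    (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])
  list(bb = bb, cs = cs, nx = nx, ny = ny, cells = cells,
       x1 = p1[, 1], y1 = p1[, 2],
       b11 = (p3[, 2] - p1[, 2]) / det, b12 = -(p3[, 1] - p1[, 1]) / det,
       b21 = -(p2[, 2] - p1[, 2]) / det, b22 = (p2[, 1] - p1[, 1]) / det)
}

# locate points (n x 2) -> list(tri = index or NA, lam = n x 3)
locate_points <- function(loc, pts, tol = 1e-9) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  n <- nrow(pts)
  tri <- rep(NA_integer_, n)
  lam <- matrix(NA_real_, n, 3)
  ix <- floor((pts[, 1] - loc$bb["xmin"]) / loc$cs) + 1L
  iy <- floor((pts[, 2] - loc$bb["ymin"]) / loc$cs) + 1L
  for (i in seq_len(n)) {
    if (is.na(ix[i]) || ix[i] < 1 || ix[i] > loc$nx ||
        iy[i] < 1 || iy[i] > loc$ny) next
    cand <- loc$cells[[(iy[i] - 1L) * loc$nx + ix[i]]]
    if (is.null(cand)) next
    dx <- pts[i, 1] - loc$x1[cand]; dy <- pts[i, 2] - loc$y1[cand]
    l2 <- loc$b11[cand] * dx + loc$b12[cand] * dy
    l3 <- loc$b21[cand] * dx + loc$b22[cand] * dy
    l1 <- 1 - l2 - l3
    ok <- which(l1 >= -tol & l2 >= -tol & l3 >= -tol)
    if (length(ok)) {
      # prefer the most interior candidate
      j <- ok[which.max(pmin(l1[ok], l2[ok], l3[ok]))]
      tri[i] <- cand[j]
      lam[i, ] <- c(l1[j], l2[j], l3[j])
    }
  }
  list(tri = tri, lam = lam)
}

# evaluate a P2 coefficient vector at located points
eval_p2 <- function(st, coef, located) {
  ok <- !is.na(located$tri)
  out <- rep(NA_real_, length(located$tri))
  if (any(ok)) {
    N <- p2_basis(located$lam[ok, , drop = FALSE])
    dofs <- st$tri_dofs[located$tri[ok], , drop = FALSE]
    vals <- matrix(coef[dofs], ncol = 6)
    out[ok] <- rowSums(N * vals)
  }
  out
}

# evaluate a P1 nodal vector at located points
eval_p1 <- function(mesh, vals, located) {
  ok <- !is.na(located$tri)
  out <- rep(NA_real_, length(located$tri))
  if (any(ok)) {
    vv <- matrix(vals[mesh$tri[located$tri[ok], , drop = FALSE]], ncol = 3)
    out[ok] <- rowSums(located$lam[ok, , drop = FALSE] * vv)
  }
  out
}

# area-weighted recovery of per-element values to nodes; `elem_vals` is
# either one value per element or an m x 3 matrix of values evaluated at
# the element's three corners
nodal_recovery <- function(mesh, elem_vals, areas = NULL) {
  if (is.null(areas)) areas <- triangle_areas(mesh$nodes, mesh$tri)
  nv <- nrow(mesh$nodes)
  num <- numeric(nv); den <- numeric(nv)
  per_corner <- !is.null(dim(elem_vals))
  for (k in 1:3) {
    idx <- mesh$tri[, k]
    v <- if (per_corner) elem_vals[, k] else elem_vals
    num <- num + unname(tapply2(idx, v * areas, nv))
    den <- den + unname(tapply2(idx, areas, nv))
  }
  num / den
}

# fast grouped sum (rowsum wrapper returning a dense length-n vector)
tapply2 <- function(idx, vals, n) {
  out <- numeric(n)
  s <- rowsum(vals, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

# solve S x = rhs with Dirichlet values fixed: x[fix] = vals
solve_with_dirichlet <- function(S, rhs, fix, vals) {
  n <- nrow(S)
  x <- numeric(n)
  x[fix] <- vals
  free <- setdiff(seq_len(n), fix)
  b <- rhs[free] - as.vector(S[free, fix, drop = FALSE] %*% vals)
  x[free] <- as.vector(Matrix::solve(S[free, free], b))
  x
}
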