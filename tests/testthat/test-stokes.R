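# Creeping-flow solver: analytic oracles, conservation, linearity.

test_that("plane Poiseuille flow is reproduced within 1% on the fine mesh", {
  g <- rect_channel_geometry(200, 40)
  m <- generate_mesh(g, "fine")
  fl <- solve_stokes(m, flow_bc(100, profile = "parabolic"))
  W <- 40; U <- 100
  ys <- c(4, 10, 20, 28, 36)
  s <- sample_flow(fl, cbind(rep(120, length(ys)), ys))
  exact <- 6 * U * (ys / W) * (1 - ys / W)
  expect_equal(s$ux_um_s, exact, tolerance = 0.01)
  expect_true(all(abs(s$uy_um_s) < 0.01 * max(exact)))
  # a plug inlet also develops towards the same parabolic profile
  fl2 <- solve_stokes(m, flow_bc(100, profile = "plug"))
  s2 <- sample_flow(fl2, cbind(rep(180, length(ys)), ys))
  expect_equal(s2$ux_um_s, exact, tolerance = 0.01)
})

test_that("zero inlet speeds give the zero solution", {
  m <- generate_mesh(rect_channel_geometry(100, 20), "coarse")
  fl <- solve_stokes(m, flow_bc(0, 0))
  expect_lt(max(abs(c(fl$ux, fl$uy))), 1e-10)
  expect_lt(max(abs(fl$p)), 1e-10)
})

test_that("Stokes linearity: scaling inlet speeds scales the solution", {
  m <- loc_mesh_coarse()
  f1 <- solve_stokes(m, flow_bc(134, 850))
  f2 <- solve_stokes(m, flow_bc(3 * 134, 3 * 850))
  expect_equal(f2$ux, 3 * f1$ux, tolerance = 1e-8)
  expect_equal(f2$uy, 3 * f1$uy, tolerance = 1e-8)
  expect_equal(f2$p, 3 * f1$p, tolerance = 1e-8)
})

test_that("mass is conserved: inlet and outlet fluxes balance to 0.1%", {
  fl <- loc_flow_normal()
  qin <- boundary_flux(fl, "blood_inlet") + boundary_flux(fl, "buffer_inlet")
  qout <- boundary_flux(fl, "outlet_PLT") + boundary_flux(fl, "outlet_CTC") +
    boundary_flux(fl, "outlet_WBC")
  expect_equal(qin, (134 + 850) * 40, tolerance = 1e-6)
  expect_lt(abs(qout - qin) / qin, 0.001)
  # weak incompressibility: the discrete divergence constraint is satisfied
  st <- fl$st
  Dv <- depchip:::assemble_divergence(fl$mesh, st, fl$geom)
  div <- as.vector(Dv$D1 %*% fl$ux + Dv$D2 %*% fl$uy)
  expect_lt(max(abs(div)) / max(abs(fl$ux)), 1e-8)
})

test_that("pressure vanishes at the outlets and is positive upstream", {
  fl <- loc_flow_normal()
  g <- loc_geom()
  for (tag in c("outlet_PLT", "outlet_CTC", "outlet_WBC")) {
    fr <- g$frames[[tag]]
    mid <- (fr$p1 + fr$p2) / 2
    s <- sample_flow(fl, matrix(mid, 1))
    expect_lt(abs(s$p_Pa), 0.01 * max(fl$p))
  }
  expect_gt(max(fl$p), 0)
})

test_that("higher buffer velocity raises the inlet-region pressure", {
  m <- loc_mesh_coarse()
  f850 <- solve_stokes(m, flow_bc(134, 850))
  f1350 <- solve_stokes(m, flow_bc(134, 1350))
  inlet_nodes <- m$nodes[, 1] < 50
  expect_gt(max(f1350$p[inlet_nodes]), max(f850$p[inlet_nodes]))
})

test_that("flow focusing pushes the blood stream to the electrode side", {
  fl <- loc_flow_normal()
  g <- loc_geom()
  # the lowest released blood streamline (10% of the inlet width from the
  # inner wall) must stay above the channel mid-line in stage 1
  fr <- g$frames$blood_inlet
  seed <- fr$p1 + 0.1 * (fr$p2 - fr$p1) + 0.5 * fr$dir
  sl <- streamlines(fl, matrix(seed, 1), t_end_s = 4)[[1]]
  mid <- sl[which(sl[, "x_um"] >= 250)[1], ]
  expect_gt(mid[["y_um"]], 20)
})

test_that("sampling honours no-slip walls, nodal identity and the domain", {
  fl <- loc_flow_normal()
  m <- fl$mesh
  s <- sample_flow(fl, c(300, 0))          # on the bottom wall
  expect_equal(abs(s$ux_um_s) + abs(s$uy_um_s), 0, tolerance = 1e-10)
  i <- which(m$nodes[, 1] > 300 & m$nodes[, 1] < 320 &
               m$nodes[, 2] > 5 & m$nodes[, 2] < 15)[1]
  s2 <- sample_flow(fl, m$nodes[i, ])
  expect_equal(s2$ux_um_s, fl$ux[i], tolerance = 1e-9)
  expect_error(sample_flow(fl, c(-500, -500)), "out-of-domain")
})

test_that("throughput obeys the global mass balance and linearity", {
  fl <- loc_flow_normal()
  g <- loc_geom()
  tot <- throughput(fl, g, "outlet_PLT") + throughput(fl, g, "outlet_CTC") +
    throughput(fl, g, "outlet_WBC")
  nominal <- (134 + 850) * 40 * 100      # (vb + vc) * CW * CD
  expect_lt(abs(tot - nominal) / nominal, 0.001)
  expect_error(throughput(fl, g, "outlet_nope"), "unknown")

  m <- loc_mesh_coarse()
  fh <- solve_stokes(m, flow_bc(67, 425))
  ff <- solve_stokes(m, flow_bc(134, 850))
  expect_equal(throughput(fh, g, "outlet_WBC"),
               throughput(ff, g, "outlet_WBC") / 2, tolerance = 1e-8)
  f0 <- solve_stokes(m, flow_bc(0, 0))
  expect_equal(throughput(f0, g, "outlet_CTC"), 0, tolerance = 1e-10)
})
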