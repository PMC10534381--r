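# Electric potential, field recovery and the DEP drive grad|E|^2.

test_that("constant Dirichlet data gives a constant potential and zero field", {
  g <- rect_channel_geometry(100, 40,
                             tags = c(left = "wall", right = "wall",
                                      top = "electrode_1",
                                      bottom = "electrode_2"))
  m <- generate_mesh(g, "coarse")
  sol <- solve_potential(m, electrode_drive(3, 2, pattern = c(1, 1)))
  expect_equal(max(abs(sol$V - 3)), 0, tolerance = 1e-10)
  expect_lt(sqrt(max(sol$e2)), 1e-8)
})

test_that("parallel-plate fixture reproduces |E| = 2 Va / gap within 0.5%", {
  g <- rect_channel_geometry(200, 40,
                             tags = c(left = "wall", right = "wall",
                                      top = "electrode_1",
                                      bottom = "electrode_2"))
  m <- generate_mesh(g, "fine")
  sol <- solve_potential(m, electrode_drive(2, 2))
  s <- sample_potential(sol, cbind(c(100, 60, 140), c(20, 10, 30)))
  expect_equal(sqrt(s$e2_V2_m2), rep(2 * 2 / 40e-6, 3), tolerance = 0.005)
  # uniform field: the DEP drive vanishes (relative to the field scale)
  drive_scale <- (1e5)^2 / 40e-6
  expect_lt(max(abs(c(s$gx_V2_m3, s$gy_V2_m3))), 1e-3 * drive_scale)
})

test_that("maximum principle and polarity antisymmetry hold on the device", {
  sol <- loc_potential_normal()
  expect_gte(min(sol$V), -2 - 1e-9)
  expect_lte(max(sol$V), 2 + 1e-9)
  m <- loc_mesh_coarse()
  sp <- solve_potential(m, electrode_drive(2, 4))
  sn <- solve_potential(m, electrode_drive(2, 4, pattern = c(-1, 1, -1, 1)))
  expect_equal(sn$V, -sp$V, tolerance = 1e-10)
  expect_equal(sn$e2, sp$e2, tolerance = 1e-9)
})

test_that("field maxima sit at the electrode corners and the field is non-uniform", {
  sol <- loc_potential_normal()
  m <- sol$mesh
  g <- m$geometry
  corners <- rbind(cbind(g$layout$el_left, 24), cbind(g$layout$el_right, 24))
  imax <- which.max(sol$e2)
  dmin <- min(sqrt((m$nodes[imax, 1] - corners[, 1])^2 +
                     (m$nodes[imax, 2] - corners[, 2])^2))
  expect_lt(dmin, 2)   # global |E| maximum within 2 um of a notch corner
  mid_channel <- m$nodes[, 2] < 10 & m$nodes[, 1] > 250 & m$nodes[, 1] < 450
  expect_gt(max(sol$e2), 10 * max(sol$e2[mid_channel]))
})

test_that("the DEP drive decays away from the electrode plane", {
  sol <- loc_potential_normal()
  g <- loc_geom()
  xg <- seq(g$layout$el_left[1], g$layout$el_right[4], by = 2)
  mag <- function(s) sqrt(s$gx_V2_m3^2 + s$gy_V2_m3^2)
  near <- max(mag(sample_potential(sol, cbind(xg, 23))))  # 1 um below faces
  deep <- max(mag(sample_potential(sol, cbind(xg, 2))))   # 22 um below
  expect_lt(deep, 0.15 * near)
})

test_that("a manufactured quadratic potential yields the exact drive field", {
  g <- rect_channel_geometry(50, 50)
  m <- generate_mesh(g, "normal")
  sol <- potential_from_values(m, function(x, y) x^2 + y^2)
  pts <- cbind(c(25, 30, 12, 40), c(25, 15, 38, 20))
  s <- sample_potential(sol, pts)
  # E = -(2x, 2y); |E|^2 = 4(x^2+y^2); grad|E|^2 = (8x, 8y) in V^2/um^3
  expect_equal(s$gx_V2_m3, 8 * pts[, 1] * 1e18, tolerance = 0.01)
  expect_equal(s$gy_V2_m3, 8 * pts[, 2] * 1e18, tolerance = 0.01)
})

test_that("doubling the voltage quadruples the drive exactly", {
  m <- loc_mesh_coarse()
  s2 <- solve_potential(m, electrode_drive(2, 4))
  s4 <- solve_potential(m, electrode_drive(4, 4))
  expect_equal(s4$gx, 4 * s2$gx, tolerance = 1e-9)
  expect_equal(s4$gy, 4 * s2$gy, tolerance = 1e-9)
})

test_that("configuration errors are raised for missing electrodes", {
  m <- generate_mesh(rect_channel_geometry(50, 20), "coarse")  # no electrodes
  expect_error(solve_potential(m, electrode_drive(2, 2)), "configuration")
  expect_error(solve_potential(loc_mesh_coarse(), electrode_drive(2, 2)),
               "configuration")
})

test_that("the drive-field object evaluates through its sampling contract", {
  sol <- loc_potential_normal()
  df <- dep_drive_field(sol)
  d <- sample_drive(df, rbind(c(300, 20), c(350, 10)))
  expect_equal(dim(d), c(2, 2))
  expect_true(all(is.finite(d)))
  s <- sample_potential(sol, c(300, 20))
  expect_equal(d[1, 1], s$gx_V2_m3)
})
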