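# Single-shell homogenization, Clausius-Mossotti factor and DEP force law.

test_that("homogeneous-sphere limit: membrane = cytoplasm collapses the shell", {
  sp <- cell_species(list(name = "X", diameter_um = 10,
                          membrane_thickness_nm = 50,
                          cytoplasm_conductivity_S_m = 0.3,
                          membrane_conductivity_S_m = 0.3,
                          cytoplasm_rel_permittivity = 60,
                          membrane_rel_permittivity = 60))
  w <- 2 * pi * 1e5
  eff <- shell_effective_permittivity(sp, w)
  expect_equal(eff$eps / EPS0_TEST, 60, tolerance = 1e-12)
  expect_equal(eff$sigma, 0.3, tolerance = 1e-12)
})

test_that("vanishing membrane thickness recovers the cytoplasm", {
  # the shell contribution scales with (t/R) * (contrast), so the limit is
  # probed with a moderate-contrast membrane at t = R * 1e-6
  R_um <- 6
  sp <- cell_species(list(name = "X", diameter_um = 2 * R_um,
                          membrane_thickness_nm = R_um * 1e3 * 1e-6,
                          cytoplasm_conductivity_S_m = 0.5,
                          membrane_conductivity_S_m = 0.05,
                          cytoplasm_rel_permittivity = 55,
                          membrane_rel_permittivity = 8))
  w <- 2 * pi * 1e5
  eff <- shell_effective_permittivity(sp, w)
  expect_equal(eff$sigma, 0.5, tolerance = 1e-4)
  expect_equal(eff$eps / EPS0_TEST, 55, tolerance = 1e-4)
})

test_that("WBC DC effective conductivity matches an independent evaluation", {
  # independent arithmetic with the catalog WBC values (d = 12 um,
  # t = 7 nm, sigma_mem = 9e-6, sigma_cyt = 0.18 S/m)
  R <- 6e-6; t <- 7e-9
  g3 <- (R / (R - t))^3
  D <- (0.18 - 9e-6) / (0.18 + 2 * 9e-6)
  sig_expect <- 9e-6 * (g3 + 2 * D) / (g3 - D)
  eff <- shell_effective_permittivity(cell_species("WBC"), 0)
  expect_equal(eff$sigma, sig_expect, tolerance = 1e-14)
  # thin insulating membrane: near the sigma_mem*(g3+2)/(g3-1) form (the
  # Delta ~ 1 approximation is good to a few percent here)
  expect_equal(eff$sigma, 9e-6 * (g3 + 2) / (g3 - 1), tolerance = 0.05)
})

test_that("membrane thicker than the radius is rejected", {
  expect_error(cell_species(list(name = "X", diameter_um = 1,
                                 membrane_thickness_nm = 600,
                                 cytoplasm_conductivity_S_m = 1,
                                 membrane_conductivity_S_m = 1,
                                 cytoplasm_rel_permittivity = 50,
                                 membrane_rel_permittivity = 5)),
               "radius")
})

test_that("CMF limits: matched particle, DC and high-frequency", {
  w <- 2 * pi * 1e5
  m <- complex_permittivity(80, 0.055, w)
  p <- complex_permittivity(80, 0.055, w)
  expect_equal(clausius_mossotti_real(p, m, w), 0)

  # conductivity-dominated limit at omega -> 0
  sp <- 0.4; sm <- 0.055
  lo <- clausius_mossotti_real(complex_permittivity(50, sp, 1e-3),
                               complex_permittivity(80, sm, 1e-3), 1e-3)
  expect_equal(lo, (sp - sm) / (sp + 2 * sm), tolerance = 1e-8)
  # exact conductivity limit via the declared DC branch
  expect_equal(clausius_mossotti_real(complex_permittivity(50, sp, 0),
                                      complex_permittivity(80, sm, 0), 0),
               (sp - sm) / (sp + 2 * sm))

  # permittivity-dominated limit at omega -> infinity (residual
  # conductivity terms scale as (sigma/(omega eps))^2 ~ 1e-7 at 1e12 rad/s)
  hi <- clausius_mossotti_real(complex_permittivity(50, sp, 1e12),
                               complex_permittivity(80, sm, 1e12), 1e12)
  expect_equal(hi, (50 - 80) / (50 + 2 * 80), tolerance = 1e-5)
})

test_that("Re K stays within [-0.5, 1] over random physical inputs", {
  set.seed(42)
  n <- 1e6
  w <- 10^runif(n, 2, 9) * 2 * pi
  ep <- complex(real = 10^runif(n, 0, 2.5) * EPS0_TEST,
                imaginary = -10^runif(n, -7, 1) / w)
  em <- complex(real = 10^runif(n, 0, 2.5) * EPS0_TEST,
                imaginary = -10^runif(n, -7, 1) / w)
  K <- Re((ep - em) / (ep + 2 * em))
  expect_true(all(K >= -0.5 - 1e-12 & K <= 1 + 1e-12))

  # and through the full shell + catalog route
  for (i in 1:200) {
    sp <- cell_species(list(name = "X",
                            diameter_um = runif(1, 1, 30),
                            membrane_thickness_nm = runif(1, 3, 20),
                            cytoplasm_conductivity_S_m = 10^runif(1, -3, 1),
                            membrane_conductivity_S_m = 10^runif(1, -8, -3),
                            cytoplasm_rel_permittivity = runif(1, 20, 100),
                            membrane_rel_permittivity = runif(1, 2, 20)))
    med <- medium_props(conductivity_S_m = 10^runif(1, -3, 0),
                        rel_permittivity = runif(1, 20, 100))
    K1 <- species_cmf(sp, med, 2 * pi * 10^runif(1, 2, 8))
    expect_gte(K1, -0.5 - 1e-12)
    expect_lte(K1, 1 + 1e-12)
  }
})

test_that("DEP force: zero in uniform fields, cubic in radius, nDEP defaults", {
  med <- medium_props()
  w <- 2 * pi * default_drive_frequency()
  expect_equal(dep_force("CTC", med, c(0, 0), w), c(0, 0))

  # cubic radius scaling of the force law, at fixed polarization contrast
  # (homogeneous sphere: the shell collapses and K is size-independent)
  drv <- c(3e14, -1e14)
  homog <- function(d) list(name = "X", diameter_um = d,
                            membrane_thickness_nm = 7,
                            cytoplasm_conductivity_S_m = 0.5,
                            membrane_conductivity_S_m = 0.5,
                            cytoplasm_rel_permittivity = 60,
                            membrane_rel_permittivity = 60)
  f1 <- dep_force(homog(8), med, drv, w)
  f2 <- dep_force(homog(16), med, drv, w)
  expect_equal(f2 / f1, c(8, 8), tolerance = 1e-12)

  # all three catalog species are nDEP at the calibrated default
  for (s in c("CTC", "WBC", "PLT"))
    expect_lt(species_cmf(s, med, w), 0)
})

test_that("force magnitudes order WBC > CTC > PLT at the default operating point", {
  expect_true(check_force_ordering(medium_props(),
                                   2 * pi * default_drive_frequency()))
  # and a violating configuration warns
  expect_warning(check_force_ordering(medium_props(conductivity_S_m = 0.03),
                                      2 * pi * 2e5),
                 "ordering")
})

test_that("catalog JSON mirrors the documented species properties", {
  cat <- cell_catalog()
  expect_setequal(cat$name, c("CTC", "WBC", "PLT"))
  ctc <- cat[cat$name == "CTC", ]
  expect_equal(ctc$diameter_um, 15)
  expect_equal(ctc$membrane_conductivity_S_m, 9e-7)
  expect_equal(cat[cat$name == "PLT", ]$membrane_thickness_nm, 8)
})

test_that("CMF spectrum export is monotone in frequency coverage and finite", {
  sp <- cmf_spectrum("WBC", medium_props(), freq_hz = 10^seq(3, 8, by = 0.25))
  expect_true(all(is.finite(sp$re_K)))
  expect_true(all(sp$re_K >= -0.5 & sp$re_K <= 1))
  # low-frequency plateau is strong nDEP, high-frequency plateau is pDEP
  expect_lt(sp$re_K[1], -0.4)
  expect_gt(sp$re_K[nrow(sp)], 0)
})
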