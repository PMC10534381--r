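# Separation efficiency, purity, sweeps and convergence reporting.

fake_assignment <- function(species, outlet, status = NULL) {
  if (is.null(status))
    status <- ifelse(outlet == "lost", "frozen_at_wall", "exited")
  df <- data.frame(id = seq_along(species), species = species,
                   outlet = outlet, status = status,
                   exit_time_s = 1, exit_speed_um_s = 100,
                   stringsAsFactors = FALSE)
  attr(df, "target_map") <- c(CTC = "outlet_CTC", WBC = "outlet_WBC",
                              PLT = "outlet_PLT")
  class(df) <- c("outlet_assignment", "data.frame")
  df
}

test_that("efficiency counts targeted cells over injected cells", {
  a <- fake_assignment(
    species = c(rep("WBC", 4), rep("CTC", 4), rep("PLT", 2)),
    outlet = c(rep("outlet_WBC", 3), "outlet_CTC",
               rep("outlet_CTC", 4), "outlet_PLT", "lost"))
  eff <- separation_efficiency(a)
  expect_equal(eff[["WBC"]], 75)
  expect_equal(eff[["CTC"]], 100)
  expect_equal(eff[["PLT"]], 50)   # lost particles stay in the denominator
})

test_that("species with no injected cells are absent, with a warning", {
  a <- fake_assignment(species = rep("WBC", 2),
                       outlet = rep("outlet_WBC", 2))
  w <- capture_warnings(eff <- separation_efficiency(a))
  expect_true(any(grepl("CTC", w)) && any(grepl("PLT", w)))
  expect_false("CTC" %in% names(eff))
  expect_equal(unname(eff["WBC"]), 100)
})

test_that("purity counts targeted over all cells at the outlet", {
  a <- fake_assignment(
    species = c("WBC", "WBC", "CTC", "CTC", "PLT"),
    outlet = c("outlet_WBC", "outlet_CTC", "outlet_CTC", "outlet_CTC",
               "lost"))
  expect_warning(pur <- outlet_purity(a), "outlet_PLT")
  expect_equal(pur[["outlet_CTC"]], 100 * 2 / 3)
  expect_equal(pur[["outlet_WBC"]], 100)
  expect_false("outlet_PLT" %in% names(pur))  # empty outlet absent
})

test_that("efficiency and purity are invariant under particle reordering", {
  set.seed(5)
  sp <- sample(c("CTC", "WBC", "PLT"), 30, replace = TRUE)
  out <- sample(c("outlet_CTC", "outlet_WBC", "outlet_PLT", "lost"),
                30, replace = TRUE)
  a1 <- fake_assignment(sp, out)
  perm <- sample.int(30)
  a2 <- fake_assignment(sp[perm], out[perm])
  expect_equal(suppressWarnings(separation_efficiency(a1)),
               suppressWarnings(separation_efficiency(a2)))
  expect_equal(suppressWarnings(outlet_purity(a1)),
               suppressWarnings(outlet_purity(a2)))
})

test_that("perfect partition with no losses is the only way to 100/100", {
  perfect <- fake_assignment(
    species = rep(c("CTC", "WBC", "PLT"), each = 2),
    outlet = rep(c("outlet_CTC", "outlet_WBC", "outlet_PLT"), each = 2))
  expect_true(all(separation_efficiency(perfect) == 100))
  expect_true(all(outlet_purity(perfect) == 100))
  one_lost <- perfect
  one_lost$outlet[1] <- "lost"
  eff <- separation_efficiency(one_lost)
  expect_lt(eff[["CTC"]], 100)
})

test_that("a degenerate single-point sweep reproduces a direct run", {
  pop <- population_spec(n_per_species = 4)
  sw <- run_sweep(widths_um = 40, voltages_V = 2, n_electrodes = 4,
                  v_buffer_um_s = 850, v_cells_um_s = 134,
                  mesh_level = "coarse", population = pop, verbose = FALSE)
  expect_equal(nrow(sw), 1)
  cfg <- run_config(bc = flow_bc(134, 850), population = pop,
                    mesh_level = "coarse")
  rep <- suppressWarnings(run_pipeline(cfg, quiet = TRUE))
  expect_equal(sw$eff_CTC, rep$efficiency_pct[["CTC"]])
  expect_equal(sw$eff_WBC, rep$efficiency_pct[["WBC"]])
  expect_equal(sw$complete_separation, rep$complete_separation)
})

test_that("sweep records failures without aborting", {
  sw <- run_sweep(widths_um = c(40, 5000), voltages_V = 2,
                  n_electrodes = 4, v_buffer_um_s = 850,
                  v_cells_um_s = 134, mesh_level = "coarse",
                  population = population_spec(n_per_species = 2),
                  verbose = FALSE)
  expect_equal(nrow(sw), 2)
  expect_true(is.na(sw$eff_CTC[2]))
  expect_match(sw$error[2], "electrode")
  expect_false(is.na(sw$eff_CTC[1]))
})

test_that("identical levels give zero mesh error and a passing report", {
  cfg <- run_config(population = population_spec(n_per_species = 3),
                    mesh_level = "coarse")
  cv <- grid_convergence(cfg, levels = c("coarse", "coarse"))
  expect_equal(unname(cv$eps_mesh_pct[1, ]), rep(0, 3))
  expect_true(cv$pass)
})
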