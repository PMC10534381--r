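# Configuration handling and the end-to-end simulation pipeline:
# geometry -> mesh -> creeping flow -> electric potential -> particle
# tracing -> separation metrics, with optional persisted artifacts.

#' Assemble a validated run configuration
#'
#' @param params A [loc_params()] (or plain list of its fields).
#' @param medium A [medium_props()].
#' @param drive An [electrode_drive()]; its electrode count must match
#'   `params$n_electrodes`.
#' @param bc A [flow_bc()].
#' @param population A [population_spec()].
#' @param settings A [tracer_settings()].
#' @param mesh_level `"coarse"`, `"normal"` or `"fine"`.
#' @param output_dir Optional directory for persisted artifacts (fields as
#'   VTU, trajectories as CSV, report as JSON).
#' @return Object of class `run_config`.
#' @export
run_config <- function(params = loc_params(),
                       medium = medium_props(),
                       drive = electrode_drive(2, 4),
                       bc = flow_bc(134, 850),
                       population = population_spec(),
                       settings = tracer_settings(),
                       mesh_level = "fine",
                       output_dir = NULL) {
  if (!inherits(params, "loc_params")) params <- do.call(loc_params, params)
  stopifnot(inherits(medium, "medium_props"),
            inherits(drive, "electrode_drive"),
            inherits(bc, "flow_bc"),
            inherits(population, "population_spec"),
            inherits(settings, "tracer_settings"))
  mesh_level <- match.arg(mesh_level, c("coarse", "normal", "fine"))
  if (drive$n_electrodes != params$n_electrodes)
    stop("schema error: drive.n_electrodes (", drive$n_electrodes,
         ") does not match geometry n_electrodes (", params$n_electrodes, ")")
  if (length(drive$pattern) != params$n_electrodes)
    stop("schema error: drive.pattern length does not match n_electrodes")
  structure(list(params = params, medium = medium, drive = drive, bc = bc,
                 population = population, settings = settings,
                 mesh_level = mesh_level, output_dir = output_dir),
            class = "run_config")
}

CONFIG_SECTIONS <- list(
  geometry = c("inlet_length_um", "main_channel_length_um",
               "secondary_channel_length_um", "channel_width_um",
               "channel_depth_um", "outlet_length_um", "inlet_angle_deg",
               "outlet_angle_deg", "electrode_protrusion_um",
               "electrode_width_um", "electrode_gap_um", "n_electrodes"),
  medium = c("dynamic_viscosity_Pa_s", "density_kg_m3", "conductivity_S_m",
             "rel_permittivity"),
  drive = c("amplitude_V", "frequency_hz", "pattern"),
  flow = c("v_blood_um_s", "v_buffer_um_s", "profile"),
  population = c("n_per_species", "species", "placement", "seed", "margin"),
  tracer = c("t_end_s", "rel_tol", "mode", "max_step_s",
             "cell_density_kg_m3", "contact"),
  mesh_level = NULL, output_dir = NULL)

#' Load a run configuration from YAML
#'
#' Unknown keys are rejected with the offending name; omitted keys take
#' the package defaults, and the returned object echoes every resolved
#' value.
#'
#' @param path YAML file path.
#' @return A validated [run_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  y <- yaml::read_yaml(path)
  unknown <- setdiff(names(y), names(CONFIG_SECTIONS))
  if (length(unknown))
    stop("schema error: unknown configuration key(s): ",
         paste(unknown, collapse = ", "))
  for (sec in c("geometry", "medium", "drive", "flow", "population",
                "tracer")) {
    bad <- setdiff(names(y[[sec]]), CONFIG_SECTIONS[[sec]])
    if (length(bad))
      stop("schema error: unknown key(s) in '", sec, "': ",
           paste(bad, collapse = ", "))
  }
  params <- do.call(loc_params, modifyList(unclass(loc_params()),
                                           y$geometry %||% list()))
  medium <- do.call(medium_props, y$medium %||% list())
  dr <- y$drive %||% list()
  drive <- electrode_drive(
    amplitude_V = dr$amplitude_V %||% 2,
    n_electrodes = params$n_electrodes,
    frequency_hz = dr$frequency_hz %||% default_drive_frequency(),
    pattern = dr$pattern)
  fl <- y$flow %||% list()
  bc <- flow_bc(fl$v_blood_um_s %||% 134, fl$v_buffer_um_s %||% 850,
                fl$profile %||% "plug")
  pop <- do.call(population_spec, y$population %||% list())
  tr <- do.call(tracer_settings, y$tracer %||% list())
  run_config(params, medium, drive, bc, pop, tr,
             mesh_level = y$mesh_level %||% "fine",
             output_dir = y$output_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run configuration to YAML
#'
#' [load_config()] of the written file reproduces the configuration
#' (round-trip identity).
#'
#' @param config A [run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(config, path) {
  y <- list(geometry = unclass(config$params),
            medium = unclass(config$medium),
            drive = list(amplitude_V = config$drive$amplitude_V,
                         frequency_hz = config$drive$frequency_hz,
                         pattern = config$drive$pattern),
            flow = list(v_blood_um_s = config$bc$v_blood_um_s,
                        v_buffer_um_s = config$bc$v_buffer_um_s,
                        profile = config$bc$profile),
            population = unclass(config$population),
            tracer = unclass(config$settings),
            mesh_level = config$mesh_level)
  if (!is.null(config$output_dir)) y$output_dir <- config$output_dir
  yaml::write_yaml(y, path)
  invisible(path)
}

config_echo <- function(config) {
  list(geometry = unclass(config$params),
       medium = unclass(config$medium),
       drive = list(amplitude_V = config$drive$amplitude_V,
                    n_electrodes = config$drive$n_electrodes,
                    frequency_hz = config$drive$frequency_hz,
                    pattern = config$drive$pattern),
       flow = list(v_blood_um_s = config$bc$v_blood_um_s,
                   v_buffer_um_s = config$bc$v_buffer_um_s,
                   profile = config$bc$profile),
       population = unclass(config$population),
       tracer = unclass(config$settings),
       mesh_level = config$mesh_level)
}

#' Run the full separation pipeline
#'
#' Executes geometry, meshing, creeping flow, electric potential, particle
#' tracing and metrics in sequence, optionally persisting fields (VTU),
#' trajectories (CSV) and the report (JSON) to `config$output_dir`.
#'
#' @param config A [run_config()] or path to a YAML configuration.
#' @param quiet Suppress stage logging?
#' @return Object of class `separation_report`: per-species efficiency
#'   (percent), per-outlet purity (percent), per-outlet throughput
#'   (um^3/s), lost-particle count, the `complete_separation` flag, the
#'   outlet assignment table, trajectories, and the full resolved
#'   configuration echo.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  t_all <- proc.time()[3]
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    r <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    say("[%s] %.2f s", name, proc.time()[3] - t0)
    r
  }
  geometry <- stage("geometry", build_loc_geometry(config$params))
  mesh <- stage("mesh", generate_mesh(geometry, config$mesh_level))
  flow <- stage("stokes", solve_stokes(mesh, config$bc, config$medium))
  potential <- NULL
  if (config$drive$amplitude_V > 0) {
    potential <- stage("electrostatics",
                       solve_potential(mesh, config$drive, config$medium))
    check_force_ordering(config$medium, config$drive$omega)
  }
  ensemble <- stage("population",
                    generate_ensemble(config$population, geometry))
  traj <- stage("tracing",
                advance_particles(flow, potential, ensemble,
                                  medium = config$medium,
                                  drive = config$drive,
                                  settings = config$settings))
  asg <- assign_outlets(traj, geometry)
  eff <- suppressWarnings(separation_efficiency(asg))
  pur <- suppressWarnings(outlet_purity(asg))
  thr <- vapply(unname(TARGET_OUTLETS), function(tag)
    throughput(flow, geometry, tag), numeric(1))
  names(thr) <- unname(TARGET_OUTLETS)
  lost <- sum(asg$outlet == "lost")
  complete <- length(eff) == length(config$population$species) &&
    all(eff >= 100 - 1e-9) && length(pur) == 3 && all(pur >= 100 - 1e-9)
  report <- structure(
    list(efficiency_pct = eff, purity_pct = pur,
         throughput_um3_s = thr, lost_count = lost,
         complete_separation = complete,
         assignment = asg, trajectories = traj,
         config = config_echo(config),
         bbox_um = geometry$bbox,
         runtime_s = unname(proc.time()[3] - t_all)),
    class = "separation_report")
  if (!is.null(config$output_dir))
    persist_report(report, flow, potential, mesh, config$output_dir)
  report
}

#' @exportS3Method base::print
print.separation_report <- function(x, ...) {
  cat("<separation_report>\n  efficiency (%):",
      paste(names(x$efficiency_pct),
            sprintf("%.2f", x$efficiency_pct), collapse = ", "), "\n")
  cat("  purity     (%):",
      paste(names(x$purity_pct), sprintf("%.2f", x$purity_pct),
            collapse = ", "), "\n")
  cat("  throughput (um^3/s):",
      paste(names(x$throughput_um3_s),
            sprintf("%.3g", x$throughput_um3_s), collapse = ", "), "\n")
  cat(sprintf("  lost: %d   complete separation: %s\n", x$lost_count,
              x$complete_separation))
  invisible(x)
}

#' Serialize a separation report to JSON
#'
#' Deterministic (timestamp-free) JSON: configuration echo, metrics and
#' the per-particle outlet table.
#'
#' @param report A [run_pipeline()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  out <- list(config = report$config,
              efficiency_pct = as.list(report$efficiency_pct),
              purity_pct = as.list(report$purity_pct),
              throughput_um3_s = as.list(report$throughput_um3_s),
              lost_count = report$lost_count,
              complete_separation = report$complete_separation,
              bbox_um = as.list(report$bbox_um),
              assignment = report$assignment[,
                c("id", "species", "outlet", "status")])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

persist_report <- function(report, flow, potential, mesh, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_report_json(report, file.path(dir, "report.json"))
  write_trajectories_csv(report$trajectories,
                         file.path(dir, "trajectories.csv"))
  write_vtu_flow(flow, file.path(dir, "flow.vtu"))
  if (!is.null(potential))
    write_vtu_potential(potential, file.path(dir, "potential.vtu"))
  invisible(dir)
}

#' The reference (optimum) device configuration
#'
#' Loads the shipped `optimum.yaml`: four electrodes at +-2.0 V, 40 um
#' channel width, buffer inlet 850 um/s, cell inlet 134 um/s, fine mesh.
#'
#' @return A [run_config()].
#' @export
optimum_config <- function() {
  load_config(system.file("extdata", "optimum.yaml", package = "depchip"))
}
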