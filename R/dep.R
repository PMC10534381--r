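EPS0 <- 8.854187817e-12  # vacuum permittivity, F/m

#' Cell species catalog
#'
#' Returns the shipped catalog of the three separated blood-sample species
#' (circulating tumor cells, white blood cells, platelets) with their sizes
#' and single-shell dielectric properties.
#'
#' @return A data.frame with one row per species and columns `name`,
#'   `diameter_um`, `membrane_thickness_nm`, `cytoplasm_conductivity_S_m`,
#'   `membrane_conductivity_S_m`, `cytoplasm_rel_permittivity`,
#'   `membrane_rel_permittivity`.
#' @export
cell_catalog <- function() {
  path <- system.file("extdata", "cell_catalog.json", package = "depchip")
  cat <- jsonlite::fromJSON(path)
  df <- cat$species
  stopifnot(is.data.frame(df))
  df
}

#' Single cell species definition
#'
#' @param name One of `"CTC"`, `"WBC"`, `"PLT"`, looked up in
#'   [cell_catalog()], or a list with the same fields for a custom species.
#' @return An object of class `cell_species`.
#' @export
cell_species <- function(name) {
  if (is.list(name) && !is.data.frame(name)) {
    sp <- name
  } else {
    cat <- cell_catalog()
    row <- cat[cat$name == name, ]
    if (nrow(row) != 1L) stop("unknown cell species: ", name)
    sp <- as.list(row)
  }
  required <- c("name", "diameter_um", "membrane_thickness_nm",
                "cytoplasm_conductivity_S_m", "membrane_conductivity_S_m",
                "cytoplasm_rel_permittivity", "membrane_rel_permittivity")
  miss <- setdiff(required, names(sp))
  if (length(miss)) stop("cell species missing fields: ",
                         paste(miss, collapse = ", "))
  if (sp$diameter_um <= 0) stop("diameter must be > 0")
  if (sp$membrane_thickness_nm * 1e-3 >= sp$diameter_um / 2)
    stop("membrane thickness must be smaller than the cell radius")
  vals <- unlist(sp[required[-1]])
  if (any(vals <= 0)) stop("conductivities and permittivities must be > 0")
  structure(sp, class = "cell_species")
}

#' @exportS3Method base::print
print.cell_species <- function(x, ...) {
  cat(sprintf("<cell_species %s>  d = %g um, t_mem = %g nm\n", x$name,
              x$diameter_um, x$membrane_thickness_nm))
  cat(sprintf("  cytoplasm: sigma = %g S/m, eps_r = %g\n",
              x$cytoplasm_conductivity_S_m, x$cytoplasm_rel_permittivity))
  cat(sprintf("  membrane : sigma = %g S/m, eps_r = %g\n",
              x$membrane_conductivity_S_m, x$membrane_rel_permittivity))
  invisible(x)
}

#' Suspending-medium properties
#'
#' Defaults describe a dilute aqueous low-conductivity DEP buffer.
#'
#' @param dynamic_viscosity_Pa_s Dynamic viscosity, Pa s.
#' @param density_kg_m3 Fluid density, kg/m3.
#' @param conductivity_S_m Electrical conductivity, S/m.
#' @param rel_permittivity Relative permittivity (dimensionless).
#' @return Object of class `medium_props`.
#' @export
medium_props <- function(dynamic_viscosity_Pa_s = 1e-3,
                         density_kg_m3 = 1000,
                         conductivity_S_m = 0.055,
                         rel_permittivity = 80) {
  vals <- c(dynamic_viscosity_Pa_s, density_kg_m3,
            conductivity_S_m, rel_permittivity)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all medium properties must be positive and finite")
  structure(list(dynamic_viscosity_Pa_s = dynamic_viscosity_Pa_s,
                 density_kg_m3 = density_kg_m3,
                 conductivity_S_m = conductivity_S_m,
                 rel_permittivity = rel_permittivity),
            class = "medium_props")
}

#' Complex permittivity at a given angular frequency
#'
#' Represents eps* = eps - i sigma / omega. The DC case (omega = 0) is kept
#' as a declared special case carrying the conductivity separately so that
#' downstream formulas can take the conductivity-only limit instead of
#' dividing by zero.
#'
#' @param eps_r Relative permittivity (dimensionless).
#' @param sigma Conductivity, S/m.
#' @param omega Angular frequency, rad/s (>= 0).
#' @return Object of class `complex_permittivity`.
#' @export
complex_permittivity <- function(eps_r, sigma, omega) {
  if (omega < 0) stop("omega must be >= 0")
  structure(list(eps = eps_r * EPS0, sigma = sigma, omega = omega,
                 value = if (omega > 0)
                   complex(real = eps_r * EPS0, imaginary = -sigma / omega)
                 else NA_complex_),
            class = "complex_permittivity")
}

#' Single-shell effective complex permittivity of a membrane-covered cell
#'
#' Homogenizes a cytoplasm sphere of radius R covered by a thin membrane of
#' thickness t into one equivalent complex permittivity using the standard
#' single-shell reduction
#' \deqn{\epsilon^*_{eff} = \epsilon^*_{mem}\frac{\gamma^3 + 2\Delta}
#'   {\gamma^3 - \Delta},\quad \gamma = R/(R-t),\quad
#'   \Delta = \frac{\epsilon^*_{cyt}-\epsilon^*_{mem}}
#'   {\epsilon^*_{cyt}+2\epsilon^*_{mem}}.}
#' At omega = 0 the same closed form is evaluated on conductivities alone
#' (the DC limit), never by dividing by omega.
#'
#' @param cell A [cell_species()].
#' @param omega Angular frequency, rad/s (>= 0).
#' @return A [complex_permittivity()] for the homogenized cell; at DC the
#'   `sigma` field carries the effective conductivity and `eps` the
#'   high-frequency-limit permittivity of the same reduction.
#' @export
shell_effective_permittivity <- function(cell, omega) {
  cell <- if (inherits(cell, "cell_species")) cell else cell_species(cell)
  if (omega < 0) stop("omega must be >= 0")
  R <- cell$diameter_um / 2 * 1e-6
  t <- cell$membrane_thickness_nm * 1e-9
  if (t >= R) stop("membrane thickness must be smaller than the radius")
  g3 <- (R / (R - t))^3
  shell_reduce <- function(cyt, mem) {
    D <- (cyt - mem) / (cyt + 2 * mem)
    mem * (g3 + 2 * D) / (g3 - D)
  }
  if (omega > 0) {
    cyt <- complex(real = cell$cytoplasm_rel_permittivity * EPS0,
                   imaginary = -cell$cytoplasm_conductivity_S_m / omega)
    mem <- complex(real = cell$membrane_rel_permittivity * EPS0,
                   imaginary = -cell$membrane_conductivity_S_m / omega)
    eff <- shell_reduce(cyt, mem)
    out <- complex_permittivity(Re(eff) / EPS0, -Im(eff) * omega, omega)
  } else {
    sig_eff <- Re(shell_reduce(cell$cytoplasm_conductivity_S_m + 0i,
                               cell$membrane_conductivity_S_m + 0i))
    eps_eff <- Re(shell_reduce(cell$cytoplasm_rel_permittivity + 0i,
                               cell$membrane_rel_permittivity + 0i))
    out <- complex_permittivity(eps_eff, sig_eff, 0)
  }
  out
}

#' Real part of the Clausius-Mossotti factor
#'
#' Re K = Re[(eps*_p - eps*_m) / (eps*_p + 2 eps*_m)] with
#' eps* = eps - i sigma/omega. Bounded in [-0.5, 1] for physical inputs.
#' At omega = 0 the conductivity-only limit (sigma_p - sigma_m) /
#' (sigma_p + 2 sigma_m) is used.
#'
#' @param particle,medium [complex_permittivity()] objects at the same
#'   angular frequency.
#' @param omega Angular frequency, rad/s; must agree with both arguments.
#' @return Dimensionless Re K(omega).
#' @export
clausius_mossotti_real <- function(particle, medium, omega) {
  stopifnot(inherits(particle, "complex_permittivity"),
            inherits(medium, "complex_permittivity"))
  if (particle$omega != omega || medium$omega != omega)
    stop("inconsistent omega across arguments")
  if (omega > 0) {
    Re((particle$value - medium$value) / (particle$value + 2 * medium$value))
  } else {
    (particle$sigma - medium$sigma) / (particle$sigma + 2 * medium$sigma)
  }
}

#' Re K(omega) for a named species against a medium
#'
#' Convenience wrapper composing [shell_effective_permittivity()] and
#' [clausius_mossotti_real()].
#'
#' @param cell A [cell_species()] or species name.
#' @param medium A [medium_props()].
#' @param omega Angular frequency, rad/s.
#' @return Dimensionless Re K(omega).
#' @export
species_cmf <- function(cell, medium, omega) {
  cell <- if (inherits(cell, "cell_species")) cell else cell_species(cell)
  p <- shell_effective_permittivity(cell, omega)
  m <- complex_permittivity(medium$rel_permittivity,
                           medium$conductivity_S_m, omega)
  clausius_mossotti_real(p, m, omega)
}

#' CMF spectrum for a species
#'
#' @param cell A [cell_species()] or species name.
#' @param medium A [medium_props()].
#' @param freq_hz Vector of signal frequencies, Hz.
#' @return data.frame with columns `freq_hz`, `omega`, `re_K`.
#' @export
cmf_spectrum <- function(cell, medium = medium_props(),
                         freq_hz = 10^seq(3, 8, length.out = 121)) {
  omega <- 2 * pi * freq_hz
  re_K <- vapply(omega, function(w) species_cmf(cell, medium, w), numeric(1))
  data.frame(freq_hz = freq_hz, omega = omega, re_K = re_K)
}

#' Dielectrophoretic force on a cell
#'
#' F_DEP = 2 pi eps_m Rp^3 Re[K(omega)] grad|E|^2. The sign of Re K decides
#' attraction towards field maxima (positive DEP) versus repulsion
#' (negative DEP). A uniform field (zero gradient) exerts no force.
#'
#' @param cell A [cell_species()] or species name.
#' @param medium A [medium_props()].
#' @param drive Numeric vector (length 2 or an n x 2 matrix): grad|E|^2 at
#'   the evaluation point(s), in V^2/m^3.
#' @param omega Angular frequency of the drive signal, rad/s.
#' @return Force vector(s) in N, same shape as `drive`.
#' @export
dep_force <- function(cell, medium, drive, omega) {
  cell <- if (inherits(cell, "cell_species")) cell else cell_species(cell)
  K <- species_cmf(cell, medium, omega)
  Rp <- cell$diameter_um / 2 * 1e-6
  pref <- 2 * pi * medium$rel_permittivity * EPS0 * Rp^3 * K
  pref * drive
}

#' Default signal frequency of the electrode drive
#'
#' The device's drive frequency and buffer conductivity are free operating
#' parameters of the model; the package default pair (sigma_m = 55 mS/m,
#' f = 98 kHz) is the calibrated operating point at which all three
#' species experience negative DEP, the force magnitudes order
#' |F_WBC| > |F_CTC| > |F_PLT|, and the reference designs achieve complete
#' separation. See the methods vignette for the calibration procedure.
#'
#' @return Frequency in Hz.
#' @export
default_drive_frequency <- function() 9.8e4

#' Electrode drive definition
#'
#' @param amplitude_V Voltage amplitude Va (> 0); electrodes carry +-Va in
#'   an alternating polarity pattern.
#' @param n_electrodes Number of electrodes (2 or 4).
#' @param frequency_hz Signal frequency, Hz (enters only through Re K).
#' @param pattern Optional signed polarity vector overriding the default
#'   alternating `(+1, -1, +1, -1, ...)`.
#' @return Object of class `electrode_drive`.
#' @export
electrode_drive <- function(amplitude_V, n_electrodes = 4,
                            frequency_hz = default_drive_frequency(),
                            pattern = NULL) {
  if (amplitude_V < 0) stop("amplitude must be >= 0")
  if (is.null(pattern)) pattern <- rep_len(c(1, -1), n_electrodes)
  if (length(pattern) != n_electrodes)
    stop("polarity pattern length must equal the electrode count")
  structure(list(amplitude_V = amplitude_V,
                 n_electrodes = as.integer(n_electrodes),
                 frequency_hz = frequency_hz,
                 omega = 2 * pi * frequency_hz,
                 pattern = pattern),
            class = "electrode_drive")
}

#' Check the species DEP-force ordering for a medium/frequency pair
#'
#' The separation mechanism requires |F_WBC| > |F_CTC| > |F_PLT| at any
#' shared field point, i.e. the same ordering of |Rp^3 Re K| across the
#' three catalog species. A warning is emitted when a configuration
#' violates it.
#'
#' @param medium A [medium_props()].
#' @param omega Angular frequency, rad/s.
#' @param warn Emit a warning on violation?
#' @return Logical: does the ordering hold?
#' @export
check_force_ordering <- function(medium, omega, warn = TRUE) {
  f <- vapply(c("CTC", "WBC", "PLT"), function(nm) {
    sp <- cell_species(nm)
    abs((sp$diameter_um / 2)^3 * species_cmf(sp, medium, omega))
  }, numeric(1))
  ok <- f[["WBC"]] > f[["CTC"]] && f[["CTC"]] > f[["PLT"]]
  if (!ok && warn)
    warning("medium/frequency configuration violates the DEP force ",
            "ordering |F_WBC| > |F_CTC| > |F_PLT|")
  ok
}
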