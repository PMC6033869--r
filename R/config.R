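# JSON configuration with field defaults, validation, and CSV formats.

#' Default configuration
#'
#' Full nested configuration with the characterised defaults: cell and
#' medium dielectrics (membrane eps_r = 4.44, sigma = 10 S/m; cytoplasm
#' eps_r = 59, sigma = 0.31 S/m; medium sigma = 0.018 S/m with eps_r = 78
#' for the aqueous sucrose buffer, configurable since it is not part of
#' the characterised set), 4.5 nm membrane thickness, 1.58 MHz carrier,
#' electrode layout (20/20 um band/gap, 50 um channel), the fitted stress
#' law and Kelvin-Voigt material, and simulation/noise settings.
#'
#' @return A nested named list.
#' @export
edeform_defaults <- function() {
  list(
    seed = 1L,
    dielectrics = list(
      membrane = list(rel_permittivity = 4.44, conductivity = 10),
      cytoplasm = list(rel_permittivity = 59, conductivity = 0.31),
      medium = list(rel_permittivity = 78, conductivity = 0.018),
      membrane_thickness_m = 4.5e-9,
      frequency_hz = 1.58e6),
    geometry = list(a_m = 3.9e-6, b_m = 3.9e-6, c_m = 1.3e-6),
    electrodes = list(
      band_width_m = 20e-6, gap_width_m = 20e-6, channel_height_m = 50e-6,
      grid_resolution_m = 0.25e-6,
      sample_d_m = 4e-6, sample_height_m = 1.3e-6),
    stress_law = list(p2 = 3.65, p1 = -2.63, p0 = 0.71, v_min = 0.5,
                      closure = "bridge"),
    material = list(
      mu_small_n_per_m = 3.02e-6, mu_exp_amp_n_per_m = 0.21e-6,
      mu_exp_rate = 2.06, mu_exp_offset_n_per_m = 0.25e-6,
      lambda_break = 1.4, t_c_s = 0.14, mu_continuity = "printed"),
    profile = list(type = "step", peak_vrms = 2, on_s = 1, off_s = 1,
                   levels_vrms = c(0.5, 1, 2), step_s = 1,
                   cycle_s = 20, half_period_s = 5),
    simulation = list(output_dt_s = 0.005, rtol = 1e-9),
    noise = list(axis_sd_m = 3.9e-8, frame_rate_hz = 100),
    synth = list(n_tracks = 20L, voltages_vrms = c(0.5, 1, 2))
  )
}

merge_config <- function(defaults, user, path = "") {
  if (!is.list(user)) return(user)
  for (key in names(user)) {
    full <- if (path == "") key else paste0(path, ".", key)
    if (!key %in% names(defaults))
      stop("unknown configuration key: '", full, "'", call. = FALSE)
    if (is.list(defaults[[key]])) {
      if (!is.list(user[[key]]))
        stop("configuration key '", full, "' must be an object",
             call. = FALSE)
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

validate_config <- function(config) {
  check_pos <- function(value, key) {
    if (!is.numeric(value) || any(!is.finite(value)) || any(value <= 0))
      stop("configuration key '", key, "' must be positive", call. = FALSE)
  }
  check_nonneg <- function(value, key) {
    if (!is.numeric(value) || any(!is.finite(value)) || any(value < 0))
      stop("configuration key '", key, "' must be >= 0", call. = FALSE)
  }
  check_pos(config$dielectrics$frequency_hz, "dielectrics.frequency_hz")
  check_pos(config$dielectrics$membrane_thickness_m,
            "dielectrics.membrane_thickness_m")
  for (layer in c("membrane", "cytoplasm", "medium")) {
    check_nonneg(config$dielectrics[[layer]]$rel_permittivity,
                 paste0("dielectrics.", layer, ".rel_permittivity"))
    check_nonneg(config$dielectrics[[layer]]$conductivity,
                 paste0("dielectrics.", layer, ".conductivity"))
  }
  check_pos(unlist(config$geometry), "geometry")
  check_pos(config$electrodes$band_width_m, "electrodes.band_width_m")
  check_pos(config$electrodes$gap_width_m, "electrodes.gap_width_m")
  check_pos(config$electrodes$channel_height_m,
            "electrodes.channel_height_m")
  check_pos(config$material$mu_small_n_per_m, "material.mu_small_n_per_m")
  check_nonneg(config$material$t_c_s, "material.t_c_s")
  if (!config$material$mu_continuity %in% c("printed", "blend"))
    stop("configuration key 'material.mu_continuity' must be \"printed\" ",
         "or \"blend\"", call. = FALSE)
  if (!config$stress_law$closure %in% c("bridge", "raw_poly"))
    stop("configuration key 'stress_law.closure' must be \"bridge\" or ",
         "\"raw_poly\"", call. = FALSE)
  if (!config$profile$type %in%
      c("step", "stepwise", "triangular", "sinusoidal", "custom"))
    stop("configuration key 'profile.type' is not a known profile type",
         call. = FALSE)
  check_pos(config$simulation$output_dt_s, "simulation.output_dt_s")
  check_nonneg(config$noise$axis_sd_m, "noise.axis_sd_m")
  check_pos(config$noise$frame_rate_hz, "noise.frame_rate_hz")
  invisible(config)
}

#' Load and validate a JSON configuration
#'
#' Reads a JSON configuration file, fills unspecified fields with
#' [edeform_defaults()], rejects unknown keys (naming the offending key),
#' and range-checks the physical parameters. With `path = NULL` the
#' defaults (optionally modified by `overrides`) are returned.
#'
#' @param path Path to a JSON file, or `NULL`.
#' @param overrides Named nested list applied on top of the file values.
#'
#' @return A validated configuration list.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  config <- edeform_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration file not found: ", path,
                                 call. = FALSE)
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    config <- merge_config(config, user)
  }
  if (length(overrides)) config <- merge_config(config, overrides)
  validate_config(config)
  config
}

#' Save a configuration as JSON
#'
#' @param config Configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# ---- object builders from a validated configuration ----

config_material <- function(config) {
  m <- config$material
  material_model(mu_small = m$mu_small_n_per_m,
                 mu_exp_amp = m$mu_exp_amp_n_per_m,
                 mu_exp_rate = m$mu_exp_rate,
                 mu_exp_offset = m$mu_exp_offset_n_per_m,
                 lambda_break = m$lambda_break, t_c = m$t_c_s,
                 mu_continuity = m$mu_continuity)
}

config_stress_law <- function(config) {
  s <- config$stress_law
  stress_law(p2 = s$p2, p1 = s$p1, p0 = s$p0, v_min = s$v_min,
             closure = s$closure)
}

config_profile <- function(config) {
  p <- config$profile
  switch(p$type,
         step = make_step_profile(p$peak_vrms, p$on_s, p$off_s),
         stepwise = make_stepwise_profile(p$levels_vrms, p$step_s),
         triangular = make_triangular_profile(p$peak_vrms, p$cycle_s),
         sinusoidal = make_sinusoidal_profile(p$peak_vrms, p$half_period_s),
         stop("custom profiles are built with make_custom_profile()",
              call. = FALSE))
}

config_geometry <- function(config) {
  g <- config$geometry
  ellipsoid_geometry(g$a_m, g$b_m, g$c_m)
}

config_cell_dielectrics <- function(config) {
  d <- config$dielectrics
  cell_dielectrics(
    dielectric_spec(d$membrane$rel_permittivity, d$membrane$conductivity),
    dielectric_spec(d$cytoplasm$rel_permittivity, d$cytoplasm$conductivity),
    d$membrane_thickness_m)
}

config_excitation <- function(config) {
  d <- config$dielectrics
  excitation_context(d$frequency_hz,
                     dielectric_spec(d$medium$rel_permittivity,
                                     d$medium$conductivity))
}

# ---- CSV formats (SI units, unit-suffixed column names) ----

#' Read a cell track from CSV
#'
#' Expects a header with columns `time_s`, `a_m`, `b_m`.
#'
#' @param path CSV path.
#' @param b0 Optional undeformed minor semi-axis in m.
#' @return A [cell_track].
#' @export
read_cell_track <- function(path, b0 = NULL) {
  df <- utils::read.csv(path)
  need <- c("time_s", "a_m", "b_m")
  if (!all(need %in% names(df)))
    stop("track CSV must have columns time_s, a_m, b_m", call. = FALSE)
  if (is.null(b0)) b0 <- df$b_m[1]
  cell_track(df$time_s, df$a_m, df$b_m, b0 = b0)
}

#' Write a cell track to CSV
#'
#' @param track A [cell_track].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_track <- function(track, path) {
  utils::write.csv(data.frame(time_s = track$time, a_m = track$a,
                              b_m = track$b),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a simulation result to CSV
#'
#' Columns: `time_s`, `vrms`, `lambda`, `strain`, `stress_n_per_m`.
#'
#' @param result A `kv_simulation`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_simulation <- function(result, path) {
  utils::write.csv(data.frame(time_s = result$time, vrms = result$voltage,
                              lambda = result$lambda, strain = result$strain,
                              stress_n_per_m = result$stress),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read an external force-vs-voltage calibration table
#'
#' Accepts force calibrations computed outside the package (for example by
#' a finite-element Maxwell-stress integration) as an alternative force
#' source; columns `voltage_vrms`, `force_newton`.
#'
#' @param path CSV path.
#' @return A data frame with a `force_of_voltage` interpolation function
#'   attached as attribute.
#' @export
read_force_table <- function(path) {
  df <- utils::read.csv(path)
  need <- c("voltage_vrms", "force_newton")
  if (!all(need %in% names(df)))
    stop("force table CSV must have columns voltage_vrms, force_newton",
         call. = FALSE)
  attr(df, "force_of_voltage") <-
    stats::approxfun(df$voltage_vrms, df$force_newton, rule = 2)
  df
}
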