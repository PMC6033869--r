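# End-to-end pipeline commands over the package functions.

#' Run a pipeline command
#'
#' Dispatches one of the package workflows and writes its artifacts to
#' `out_dir`: `"simulate"` (forward simulation CSV under the configured
#' profile), `"synth"` (synthetic noisy tracks plus a manifest JSON),
#' `"fit"` (material recovery from tracks listed in a manifest),
#' `"energy"` (hysteresis-energy table CSV), `"field"` (field-gradient map
#' CSV). The resolved configuration, package version and seed are logged
#' to `run_config.json`; a fixed configuration and seed give byte-identical
#' CSV outputs.
#'
#' @param command One of `"simulate"`, `"fit"`, `"energy"`, `"synth"`,
#'   `"field"`.
#' @param config A configuration list from [load_config()].
#' @param out_dir Output directory (created if missing).
#' @param manifest For `"fit"`: path to a manifest JSON as written by
#'   `"synth"` (fields `tracks`: per-track CSV paths and voltages).
#'
#' @return Named character vector of the files written, invisibly.
#' @export
run_pipeline <- function(command, config = load_config(), out_dir = ".",
                         manifest = NULL) {
  commands <- c("simulate", "fit", "energy", "synth", "field")
  if (!is.character(command) || length(command) != 1L ||
      !command %in% commands)
    stop("unknown command; use one of: ",
         paste(commands, collapse = ", "), call. = FALSE)
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  log_path <- file.path(out_dir, "run_config.json")
  save_config(c(config,
                list(package_version =
                       as.character(utils::packageVersion("edeform")),
                     command = command)),
              log_path)
  files["config"] <- log_path

  material <- config_material(config)
  law <- config_stress_law(config)

  if (command == "simulate") {
    profile <- config_profile(config)
    sim <- simulate_cell(material, profile, law,
                         output_dt = config$simulation$output_dt_s,
                         rtol = config$simulation$rtol)
    p <- file.path(out_dir, "simulation.csv")
    write_simulation(sim, p)
    files["simulation"] <- p
  } else if (command == "energy") {
    tab <- energy_table(material, law,
                        cycle = config$profile$cycle_s,
                        half_period = config$profile$half_period_s,
                        output_dt = config$simulation$output_dt_s)
    p <- file.path(out_dir, "energy.csv")
    utils::write.csv(tab, p, row.names = FALSE)
    files["energy"] <- p
  } else if (command == "synth") {
    voltages <- rep_len(config$synth$voltages_vrms, config$synth$n_tracks)
    entries <- list()
    for (k in seq_len(config$synth$n_tracks)) {
      profile <- make_step_profile(voltages[k], config$profile$on_s,
                                   config$profile$off_s)
      noise <- noise_spec(config$noise$axis_sd_m, config$noise$frame_rate_hz,
                          seed = config$seed + k)
      track <- generate_track(material, profile, law,
                              b0 = config$geometry$b_m,
                              a0 = config$geometry$a_m, noise = noise)
      p <- file.path(out_dir, sprintf("track_%03d.csv", k))
      write_cell_track(track, p)
      files[sprintf("track_%03d", k)] <- p
      entries[[k]] <- list(file = basename(p), voltage_vrms = voltages[k],
                           seed = config$seed + k)
    }
    mp <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(list(tracks = entries,
                              b0_m = config$geometry$b_m,
                              on_s = config$profile$on_s,
                              off_s = config$profile$off_s),
                         mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files["manifest"] <- mp
  } else if (command == "fit") {
    if (is.null(manifest))
      stop("'fit' needs a manifest JSON (see the 'synth' command)",
           call. = FALSE)
    man <- jsonlite::read_json(manifest, simplifyVector = FALSE)
    base <- dirname(manifest)
    tracks <- list(); profiles <- list()
    for (e in man$tracks) {
      tracks[[length(tracks) + 1L]] <-
        read_cell_track(file.path(base, e$file), b0 = man$b0_m)
      profiles[[length(profiles) + 1L]] <-
        make_step_profile(e$voltage_vrms, man$on_s, man$off_s)
    }
    fit <- recover_material(tracks, profiles, law)
    p <- file.path(out_dir, "material.json")
    cf <- as.list(coef(fit))
    jsonlite::write_json(c(cf, list(dispersion = as.list(fit$dispersion),
                                    n_tracks = fit$n_tracks)),
                         p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files["material"] <- p
  } else if (command == "field") {
    layout <- electrode_layout(config$electrodes$band_width_m,
                               config$electrodes$gap_width_m,
                               config$electrodes$channel_height_m)
    map <- solve_interdigitated_field(layout,
                                      config$electrodes$grid_resolution_m)
    p <- file.path(out_dir, "field_map.csv")
    utils::write.csv(
      data.frame(x_m = rep(map$x, times = length(map$z)),
                 z_m = rep(map$z, each = length(map$x)),
                 grad_e2_v2_per_m3 = as.vector(map$grad_e2)),
      p, row.names = FALSE)
    files["field_map"] <- p
  }
  invisible(files)
}
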