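# Flat key/value run configuration. One `key = value` pair per line, `#`
# comments allowed; comma-separated values become numeric vectors. The same
# schema is emitted as the run manifest, so a manifest can be fed back in as
# a config to reproduce a run exactly.

default_run_config <- function() {
  list(
    experiment = "targeting_sweep",
    # geometry
    cell_radius = 6000, membrane_thickness = 10, nucleus_radius = 3300,
    n_mitochondria = 90, mitochondrion_radius = 463,
    # nanoparticles
    n_np = 10000, r_np = 5, fraction_targeted = 0, target = "nucleus",
    # source
    source_mode = "discrete", gold_mass_percent = 0.001,
    half_life_days = 2.7, isotope_mass = 198,
    beta_energies = c(961, 285), beta_intensities = c(0.99, 0.01),
    gamma_energies = c(412, 676, 1088),
    gamma_intensities = c(0.96, 0.01, 0.01),
    # transport
    step_fraction = 0.05, energy_cutoff = 1, multiple_scattering = TRUE,
    photon_mode = "single_interaction", max_step = 10000,
    monoenergetic_beta = FALSE,
    # run control
    n_decays = 1e5, n_batches = 10, base_seed = 1,
    x_values = seq(0, 1, by = 0.2),
    output_dir = "celldosim-out"
  )
}

config_error <- function(msg) {
  abort(msg, class = "celldosim_config_error")
}

coerce_config_value <- function(key, value, template) {
  parts <- trimws(strsplit(value, ",")[[1]])
  tmpl <- template[[key]]
  if (is.logical(tmpl)) {
    lv <- tolower(parts)
    if (!all(lv %in% c("true", "false"))) {
      config_error(sprintf("config key '%s' expects true/false, got '%s'",
                           key, value))
    }
    return(lv == "true")
  }
  if (is.numeric(tmpl)) {
    num <- suppressWarnings(as.numeric(parts))
    if (any(is.na(num))) {
      config_error(sprintf("config key '%s' expects a number, got '%s'",
                           key, value))
    }
    return(num)
  }
  paste(parts, collapse = ",")
}

#' Read a run configuration file
#'
#' Parses a flat `key = value` text file against the documented schema and
#' fills unset keys with their defaults. Unknown keys are an error naming
#' the key.
#'
#' @param path Path to the configuration file, or `NULL` for the defaults.
#' @return A named list (class `run_config`).
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      config_error(sprintf("config file not found: %s", path))
    }
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      if (!grepl("=", ln, fixed = TRUE)) {
        config_error(sprintf("malformed config line (expected key = value): '%s'",
                             ln))
      }
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      if (!key %in% names(cfg)) {
        config_error(sprintf("unknown config key '%s'", key))
      }
      cfg[[key]] <- coerce_config_value(key, val, default_run_config())
    }
  }
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  experiments <- c("continuous_sweep", "discrete_radii", "targeting_sweep",
                   "mass_independence")
  if (!cfg$experiment %in% experiments) {
    config_error(sprintf("unknown experiment '%s' (expected one of %s)",
                         cfg$experiment,
                         paste(experiments, collapse = ", ")))
  }
  if (cfg$n_batches < 1) config_error("n_batches must be >= 1")
  if (cfg$n_decays < 1) config_error("n_decays must be >= 1")
  if (cfg$fraction_targeted < 0 || cfg$fraction_targeted > 1) {
    config_error("fraction_targeted must lie in [0, 1]")
  }
  if (!cfg$target %in% c("nucleus", "mitochondria")) {
    config_error(sprintf("unknown target '%s'", cfg$target))
  }
  if (!cfg$source_mode %in% c("discrete", "continuous")) {
    config_error(sprintf("unknown source_mode '%s'", cfg$source_mode))
  }
  if (!cfg$photon_mode %in% c("single_interaction", "escape")) {
    config_error(sprintf("unknown photon_mode '%s'", cfg$photon_mode))
  }
  invisible(cfg)
}

#' Write a run configuration (or manifest) file
#'
#' Serialises the configuration in the same flat key/value format that
#' [read_run_config()] parses, so re-running from the emitted manifest
#' reproduces the outputs exactly.
#'
#' @param cfg A `run_config` list.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  fmt <- function(v) {
    if (is.logical(v)) return(paste(ifelse(v, "true", "false"),
                                    collapse = ","))
    if (is.numeric(v)) return(paste(sprintf("%.17g", v), collapse = ","))
    paste(v, collapse = ",")
  }
  keys <- names(default_run_config())
  writeLines(sprintf("%s = %s", keys,
                     vapply(cfg[keys], fmt, character(1))), path)
  invisible(path)
}

config_nuclide <- function(cfg) {
  nuclide_spec(
    name = "config", isotope_mass = cfg$isotope_mass,
    half_life_days = cfg$half_life_days,
    beta_lines = tibble::tibble(energy_kev = cfg$beta_energies,
                                intensity = cfg$beta_intensities),
    gamma_lines = tibble::tibble(energy_kev = cfg$gamma_energies,
                                 intensity = cfg$gamma_intensities)
  )
}

config_transport <- function(cfg) {
  transport_config(
    step_fraction = cfg$step_fraction, energy_cutoff = cfg$energy_cutoff,
    multiple_scattering = cfg$multiple_scattering,
    photon_mode = cfg$photon_mode, max_step = cfg$max_step,
    monoenergetic_beta = cfg$monoenergetic_beta
  )
}

config_geometry <- function(cfg) {
  build_cho_cell(
    cell_radius = cfg$cell_radius,
    membrane_thickness = cfg$membrane_thickness,
    nucleus_radius = cfg$nucleus_radius,
    n_mitochondria = cfg$n_mitochondria,
    mitochondrion_radius = cfg$mitochondrion_radius
  )
}
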