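## Configuration, validation and run manifests.  One YAML file fully
## specifies a run; defaults are the printed physical parameters (material,
## CSF properties, production/absorption split).  Unknown keys are rejected
## with a nearest-match suggestion so typos never silently fall back to a
## default.

#' Default run configuration
#'
#' All defaults filled in: idealized geometry, the validated brain-tissue
#' constants (E = 584.4 Pa, nu = 0.35, permeability 4.08e-12, void ratio
#' 0.2, Prony tau 3.1/27/410 s, g 0.285), CSF properties (mu = 0.001,
#' rho = 998.2), the 0.35 / 0.17 / 0.18 ml/min flow split, coupling
#' controls, synthetic-cohort design and analysis threshold.
#'
#' @return Nested named list (class \code{run_config}).
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    output_dir = "icpfsi-output",
    effective_depth_m = 0.02,
    geometry = list(ventricle_radius_mm = 20, brain_outer_radius_mm = 70,
                    sas_thickness_mm = 3, aqueduct_radius_mm = 0,
                    inlet_radius_mm = 2, refinement_level = "coarse",
                    base_h_mm = 16),
    material = list(youngs_modulus_Pa = 584.4, poisson_ratio = 0.35,
                    permeability_m4_Ns = 4.08e-12, void_ratio = 0.2,
                    density_kg_m3 = 1000,
                    prony_relaxation_times_s = c(3.1, 27, 410),
                    prony_moduli = c(0.285, 0.285, 0.285),
                    prony_mode = "per_term"),
    fluid = list(density_kg_m3 = 998.2, dynamic_viscosity_Pa_s = 0.001),
    flows = list(inlet_ml_min = 0.35, spinal_ml_min = 0.17,
                 sinus_ml_min = 0.18),
    waveform = list(heart_rate_bpm = 70, n_samples = 64),
    coupling = list(max_subiterations = 60, interface_tolerance = 1e-4,
                    relaxation_factor = 0.3, dt_s = NA, n_cycles = 3,
                    outlet_pressure_cmH2O = 5,
                    outlet_mode = "sinus_pressure"),
    cohort = list(n_patients = 14, n_stages = 8,
                  baseline_icp_range_cmH2O = c(20, 30),
                  post_shunt_decline = 0.35, oscillation_amplitude = 0.08,
                  heart_rate_range_bpm = c(60, 90)),
    analysis = list(alpha = 0.05, interval_mode = "consecutive")),
    class = "run_config")
}

## recursive unknown-key validation with nearest-match suggestions
check_keys <- function(user, ref, path = "") {
  if (!is.list(user)) return(invisible(NULL))
  unknown <- setdiff(names(user), names(ref))
  if (length(unknown)) {
    key <- unknown[1]
    sugg <- names(ref)[utils::adist(key, names(ref)) <=
                         max(2, nchar(key) %/% 3)]
    stop("unknown config key '", paste0(path, key), "'",
         if (length(sugg)) paste0("; did you mean '", sugg[1], "'?") else "",
         call. = FALSE)
  }
  for (nm in names(user))
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])))
      check_keys(user[[nm]], ref[[nm]], paste0(path, nm, "."))
  invisible(NULL)
}

#' Load, validate and complete a run configuration
#'
#' Reads YAML, rejects unknown keys (with a suggestion), and fills every
#' missing field from \code{\link{default_config}}.  An empty file yields
#' the pure defaults.
#'
#' @param path YAML file path.
#' @return A validated \code{run_config}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  ref <- default_config()
  check_keys(user, ref)
  cfg <- utils::modifyList(ref, user)
  class(cfg) <- "run_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(cfg$effective_depth_m > 0,
            cfg$fluid$density_kg_m3 > 0,
            cfg$fluid$dynamic_viscosity_Pa_s > 0,
            cfg$material$youngs_modulus_Pa > 0)
  if (abs(cfg$flows$inlet_ml_min -
          (cfg$flows$spinal_ml_min + cfg$flows$sinus_ml_min)) > 1e-9)
    stop("flow constants must balance: inlet = spinal + sinus")
  invisible(cfg)
}

#' Write a configuration to YAML
#'
#' @param cfg a \code{run_config}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Stable hash of a configuration
#'
#' MD5 of the canonical YAML dump; recorded in run manifests so outputs are
#' traceable to their exact configuration.
#'
#' @param cfg a \code{run_config}.
#' @return Character MD5 digest.
#' @export
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(unclass(cfg), tf)
  unname(tools::md5sum(tf))
}

#' Write a run manifest
#'
#' @param dir output directory (created if needed).
#' @param cfg the configuration used.
#' @param seed integer seed of the run.
#' @param wall_time_s elapsed seconds.
#' @param extra optional named list merged into the manifest.
#' @return Path of the manifest JSON, invisibly.
#' @export
write_manifest <- function(dir, cfg, seed, wall_time_s = NA_real_,
                           extra = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- c(list(
    package = "icpfsi",
    version = as.character(utils::packageVersion("icpfsi")),
    r_version = R.version.string,
    config_hash = config_hash(cfg),
    seed = seed,
    wall_time_s = wall_time_s,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")), extra)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

## constructors from a config block
config_geometry <- function(cfg) {
  g <- cfg$geometry
  head_geometry(ventricle_radius = g$ventricle_radius_mm,
                brain_outer_radius = g$brain_outer_radius_mm,
                sas_thickness = g$sas_thickness_mm,
                aqueduct_radius = g$aqueduct_radius_mm,
                inlet_radius = g$inlet_radius_mm)
}

config_material <- function(cfg) {
  m <- cfg$material
  poro_viscoelastic_material(
    youngs_modulus = m$youngs_modulus_Pa, poisson_ratio = m$poisson_ratio,
    permeability = m$permeability_m4_Ns, void_ratio = m$void_ratio,
    density = m$density_kg_m3,
    prony_relaxation_times = m$prony_relaxation_times_s,
    prony_moduli = m$prony_moduli, prony_mode = m$prony_mode)
}

config_fluid <- function(cfg) {
  fluid_properties(density = cfg$fluid$density_kg_m3,
                   dynamic_viscosity = cfg$fluid$dynamic_viscosity_Pa_s)
}

config_coupling <- function(cfg) {
  cc <- cfg$coupling
  coupling_config(max_subiterations = cc$max_subiterations,
                  interface_tolerance = cc$interface_tolerance,
                  relaxation_factor = cc$relaxation_factor,
                  dt = if (is.null(cc$dt_s) || is.na(cc$dt_s)) NULL
                       else cc$dt_s,
                  n_cycles = cc$n_cycles,
                  outlet_pressure = cc$outlet_pressure_cmH2O,
                  outlet_mode = cc$outlet_mode)
}

config_waveform_triplet <- function(cfg, seed = cfg$seed) {
  hr <- cfg$waveform$heart_rate_bpm; ns <- cfg$waveform$n_samples
  list(
    inlet = generate_pulsatile_waveform(hr, cfg$flows$inlet_ml_min,
                                        n_samples = ns, seed = seed,
                                        site = "ventricular_inlet"),
    spinal = generate_pulsatile_waveform(hr, cfg$flows$spinal_ml_min,
                                         n_samples = ns, seed = seed + 1L,
                                         site = "spinal_outlet"),
    sinus = generate_pulsatile_waveform(hr, cfg$flows$sinus_ml_min,
                                        n_samples = ns, seed = seed + 2L,
                                        site = "sinus_outlet"))
}

#' Run one coupled simulation from a configuration
#'
#' Convenience wrapper binding the pipeline together: geometry, mesh,
#' synthetic boundary waveforms (seeded), coupled FSI solve.
#'
#' @param cfg a \code{run_config}.
#' @param refinement_level override of the configured level.
#' @param verbose forwarded to \code{\link{run_fsi}}.
#' @return An \code{fsi_result}.
#' @export
simulate_from_config <- function(cfg = default_config(),
                                 refinement_level = NULL,
                                 verbose = FALSE) {
  validate_config(cfg)
  lev <- if (is.null(refinement_level)) cfg$geometry$refinement_level
         else refinement_level
  mesh <- generate_mesh(config_geometry(cfg), lev,
                        base_h = cfg$geometry$base_h_mm)
  run_fsi(mesh, config_fluid(cfg), config_material(cfg),
          config_waveform_triplet(cfg), config_coupling(cfg),
          effective_depth = cfg$effective_depth_m, verbose = verbose)
}
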