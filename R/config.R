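#' Default run configuration
#'
#' A nested list holding every tunable parameter of the pipeline: gait
#' landmarks, cohort anthropometrics, kinematic variability, the master seed,
#' the ligament parameters, the knee coupling table and default-pose origin
#' offset, the frame side, the insertion-site grid magnitudes, peak-detection
#' windows, significance levels, and the literature ultimate-force annotation
#' threshold. The configuration round-trips losslessly through
#' [save_config()] / [load_config()].
#'
#' @return A list of class `acltis_config`.
#' @export
default_config <- function() {
  structure(
    list(
      landmarks = list(
        stance_flexion_max = 14, swing_flexion_max = 64,
        adduction_peak = 10, adduction_peak_time = 0.85,
        swing_internal_rot_max = 7, swing_external_rot_max = 12,
        stance_fraction = 0.60
      ),
      cohort = list(
        n_subjects = 7L,
        height_mean = 1.63, height_sd = 0.098,
        mass_mean = 72.04, mass_sd = 15.22,
        generic_height = 1.70
      ),
      variability = 1,
      master_seed = 42L,
      ligament = list(
        # generic-model ACL: insertions in cm, L0 cm, k N, e_l dimensionless
        femoral_insertion = c(-1.1, -40.5, 0.7),
        tibial_insertion = c(1.2, -3.2, -0.1),
        resting_length = 2.8,
        stiffness = 3100,
        linear_strain_limit = 0.03
      ),
      coupling = list(
        # generic stand-in coupling table (flexion deg; tx, ty cm),
        # calibrated so the default center condition is taut in stance
        flexion = c(0, 15, 30, 60, 90, 120),
        tx = c(0, -0.08, -0.16, -0.32, -0.44, -0.52),
        ty = rep(0.80, 6),
        method = "linear"
      ),
      knee = list(
        origin_offset = c(0, -40, 0) # femoral head -> epicondyle midpoint, cm
      ),
      side = "right",
      grid_magnitudes_mm = c(2.5, 5, 7.5),
      peak_split = 0.30,
      significance_levels = c(0.05, 0.01),
      ultimate_force_annotation_N = 600,
      output_dir = "acltis-output"
    ),
    class = "acltis_config"
  )
}

config_ligament_spec <- function(config) {
  do.call(ligament_spec, config$ligament)
}

config_coupling <- function(config) {
  knee_coupling(
    knots = data.frame(
      flexion = config$coupling$flexion,
      tx = config$coupling$tx,
      ty = config$coupling$ty
    ),
    method = config$coupling$method
  )
}

config_landmarks <- function(config) {
  do.call(gait_landmarks, config$landmarks)
}

#' Generate the cohort described by a configuration
#'
#' @param config Configuration list, see [default_config()].
#' @param master_seed Optional seed overriding the configured one.
#' @return A `gait_cohort`, see [generate_cohort()].
#' @export
cohort_from_config <- function(config = default_config(), master_seed = NULL) {
  validate_config(config)
  seed <- if (is.null(master_seed)) config$master_seed else as.integer(master_seed)
  generate_cohort(
    n_subjects = config$cohort$n_subjects,
    landmarks = config_landmarks(config),
    height_mean = config$cohort$height_mean,
    height_sd = config$cohort$height_sd,
    mass_mean = config$cohort$mass_mean,
    mass_sd = config$cohort$mass_sd,
    variability = config$variability,
    master_seed = seed,
    generic_height = config$cohort$generic_height
  )
}

validate_config <- function(config) {
  stopifnot(is.list(config))
  config_landmarks(config)
  config_ligament_spec(config)
  config_coupling(config)
  frame_convention(config$side)
  stopifnot(
    length(config$knee$origin_offset) == 3L,
    all(config$grid_magnitudes_mm > 0),
    config$peak_split > 0,
    config$peak_split < config$landmarks$stance_fraction,
    config$cohort$n_subjects >= 1
  )
  invisible(config)
}

#' Save / load a run configuration (YAML)
#'
#' @param config A configuration list from [default_config()].
#' @param path File path for the YAML document.
#' @return `load_config()` returns the configuration list; `save_config()`
#'   returns `path` invisibly.
#' @export
save_config <- function(config, path) {
  validate_config(config)
  plain <- unclass(config)
  yaml::write_yaml(plain, path, precision = 15)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  config <- utils::modifyList(unclass(default_config()), raw)
  config$master_seed <- as.integer(config$master_seed)
  config$cohort$n_subjects <- as.integer(config$cohort$n_subjects)
  class(config) <- "acltis_config"
  validate_config(config)
  config
}
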