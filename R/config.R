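# Configuration: schema, defaults (the printed parameter set of the study
# protocols), validation, and YAML round-trip.

#' Default simulation configuration
#'
#' Nested list of every tunable with the protocol defaults: 300 x 300 grid
#' at dx = 0.3125 mm, dt = 0.01 ms, axial coupling 1.28 nS/pF at 7:1
#' anisotropy, stimulus -12.5 pA/pF for 5 ms, fibrotic removal fractions
#' 0.8 (transverse) / 0.2 (longitudinal), SR-load reset 1.0 mM, 5
#' pre-pacing beats, and 30 trials per condition.
#'
#' @return the configuration list.
#' @export
default_config <- function() {
  list(
    grid = list(nx = 300L, ny = 300L, dx = 0.3125),
    time = list(dt = 0.01, trial_duration = 1000, follow_up = 2000),
    cell = list(model_variant = "minimal", af = FALSE, iso = FALSE,
                fibroblast_coupling = FALSE),
    srf = list(mode = "static", sigma_ti = 0.5, sigma_lambda = 0.5,
               ca_sr = 1.0, ca_threshold = 0.9),
    substrate = list(orientation = "OY", fibrosis = FALSE, patch_seed = 10,
                     area_fraction = 0.25, p_transverse = 0.8,
                     p_longitudinal = 0.2),
    coupling = list(g_a = 1.28, anisotropy_ratio = 7),
    protocol = list(type = "pta", cycle_length = 400, pre_pace_beats = 5L,
                    n_trials = 30L, stimulus_site = "centre",
                    stimulus_amplitude = -12.5, stimulus_duration = 5,
                    stimulus_radius = 5L, sr_reset = 1.0),
    output = list(dir = ".", snapshot_dt = 0),
    seeds = list(master = 1L)
  )
}

.check_range <- function(value, field, lo = -Inf, hi = Inf,
                         strict_lo = FALSE) {
  if (!is.numeric(value) || length(value) != 1 || !is.finite(value) ||
      value < lo || value > hi || (strict_lo && value <= lo))
    stop("configuration field '", field, "' violates its constraint (",
         if (strict_lo) paste0("> ", lo) else paste0("[", lo, ", ", hi, "]"),
         "): ", value)
  invisible(value)
}

.validate_config <- function(cfg) {
  .check_range(cfg$grid$nx, "grid.nx", 2)
  .check_range(cfg$grid$ny, "grid.ny", 2)
  .check_range(cfg$grid$dx, "grid.dx", 0, strict_lo = TRUE)
  .check_range(cfg$time$dt, "time.dt", 0, strict_lo = TRUE)
  .check_range(cfg$srf$sigma_ti, "srf.sigma_ti", 0, 1)
  .check_range(cfg$srf$sigma_lambda, "srf.sigma_lambda", 0, 1)
  .check_range(cfg$substrate$area_fraction, "substrate.area_fraction", 0, 1)
  .check_range(cfg$substrate$p_transverse, "substrate.p_transverse", 0, 1)
  .check_range(cfg$substrate$p_longitudinal, "substrate.p_longitudinal", 0, 1)
  .check_range(cfg$coupling$g_a, "coupling.g_a", 0)
  .check_range(cfg$coupling$anisotropy_ratio, "coupling.anisotropy_ratio", 0,
               strict_lo = TRUE)
  .check_range(cfg$protocol$cycle_length, "protocol.cycle_length",
               cfg$protocol$stimulus_duration, strict_lo = TRUE)
  .check_range(cfg$protocol$n_trials, "protocol.n_trials", 1)
  .check_range(cfg$protocol$sr_reset, "protocol.sr_reset", 0,
               strict_lo = TRUE)
  if (!cfg$srf$mode %in% c("static", "dynamic"))
    stop("configuration field 'srf.mode' must be 'static' or 'dynamic'")
  if (!cfg$substrate$orientation %in% c("OY", "control", "remodelled"))
    stop("configuration field 'substrate.orientation' must be one of ",
         "OY / control / remodelled")
  invisible(cfg)
}

# recursive defaults merge that rejects unknown keys
.merge_config <- function(base, user, path = "") {
  for (nm in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(base))
      stop("unknown configuration field '", full, "'")
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], user[[nm]], full)
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Load a simulation configuration from a YAML file
#'
#' Unset fields take the protocol defaults ([default_config()]); unknown
#' fields and constraint violations raise an error naming the field.  An
#' empty file yields the full default configuration.
#'
#' @param path YAML file path.
#' @return the validated configuration list (class `sim_config`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- .merge_config(default_config(), user)
  .validate_config(cfg)
  structure(cfg, class = "sim_config")
}

#' Save a configuration to YAML
#'
#' @param cfg a configuration list.
#' @param path output path.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
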