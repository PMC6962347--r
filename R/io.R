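#' Write a wave field or IQ ensemble to a portable array container
#'
#' The container is a single-file serialized list with a fixed contract:
#' dataset `velocity` (real) or `iq` (complex) in (depth, lateral,
#' slow_time) axis order, an optional boolean `roi` mask (depth x
#' lateral), and every acquisition-grid field as a named attribute in SI
#' units. Anything honouring this contract (for example a converter from
#' a vendor export) can feed the pipeline.
#'
#' @param x A [particle_velocity_field()] or [iq_ensemble()].
#' @param path Output file path.
#' @param roi Optional [roi_mask()] stored alongside the data.
#' @return `path`, invisibly.
#' @export
write_wavefield <- function(x, path, roi = NULL) {
  payload <- list(format = "plaquewave-container", version = 1L)
  if (inherits(x, "particle_velocity_field")) {
    payload$velocity <- x$values
    payload$times <- x$times
    payload$grid <- unclass(x$grid)
  } else if (inherits(x, "iq_ensemble")) {
    payload$iq <- x$samples
    payload$grid <- unclass(x$grid)
  } else {
    stop("x must be a particle_velocity_field or iq_ensemble", call. = FALSE)
  }
  if (!is.null(roi)) {
    stopifnot(inherits(roi, "roi_mask"))
    payload$roi <- roi$mask
  }
  saveRDS(payload, path)
  invisible(path)
}

#' Read a wave field or IQ ensemble container
#'
#' @param path File written by [write_wavefield()].
#' @return A list with element `data` (a [particle_velocity_field()] or
#'   [iq_ensemble()]) and `roi` (an [roi_mask()] or `NULL`).
#' @export
read_wavefield <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$format, "plaquewave-container")) {
    stop("not a plaquewave array container: ", path, call. = FALSE)
  }
  grid <- do.call(acquisition_grid, payload$grid[c(
    "depth_spacing", "lateral_spacing", "n_depth", "n_lateral",
    "frame_interval", "n_frames", "center_frequency", "sound_speed"
  )])
  data <- if (!is.null(payload$velocity)) {
    particle_velocity_field(payload$velocity, grid, payload$times)
  } else if (!is.null(payload$iq)) {
    iq_ensemble(payload$iq, grid)
  } else {
    stop("container holds neither 'velocity' nor 'iq'", call. = FALSE)
  }
  roi <- if (!is.null(payload$roi)) roi_mask(payload$roi) else NULL
  list(data = data, roi = roi)
}

#' Write a cohort table to CSV
#'
#' One row per plaque and view; missing covariate values are written as
#' empty cells.
#'
#' @param cohort A `cohort_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cohort table from CSV, validating the fixed schema
#'
#' @param path CSV written by [write_cohort_csv()] (or an external table
#'   honouring the same schema: `plaque_id`, `subject_id`, `view`,
#'   `aha_type`, `<metric>_mean/_sd/_n` per velocity metric, one column
#'   per covariate; empty cells are missing values).
#' @param metrics Velocity metrics whose summary columns must be present.
#' @return A `cohort_table` data.frame.
#' @export
read_cohort_csv <- function(path, metrics = c("gv", "pv200", "pv300", "pv400")) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(cohort, metrics)
  class(cohort) <- c("cohort_table", "data.frame")
  cohort
}

#' Load and validate a pipeline configuration from YAML
#'
#' The configuration has one block per stage (`grid`, `simulation`,
#' `motion`, `group_velocity`, `phase_velocity`, `cohort`) plus a global
#' `seed`; unknown keys anywhere are rejected so typos cannot silently
#' fall back to defaults.
#'
#' @param path YAML file path.
#' @return A validated nested list of class `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pipeline_config_from_list(raw)
}

#' Build a pipeline configuration from a nested list
#'
#' @param raw Nested list as produced by [load_pipeline_config()] or
#'   built in code; see that function for the block structure.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_list <- function(raw = list()) {
  known_top <- c(
    "seed", "n_plaques", "acquisitions_per_plaque", "grid",
    "simulation", "motion", "group_velocity", "phase_velocity"
  )
  check_keys(raw, known_top, "top level")
  cfg <- list(
    seed = raw$seed %||% 1L,
    n_plaques = raw$n_plaques %||% 4L,
    acquisitions_per_plaque = raw$acquisitions_per_plaque %||% 3L,
    grid = raw$grid %||% list(),
    simulation = raw$simulation %||% list(),
    motion = raw$motion %||% list(),
    group_velocity = raw$group_velocity %||% list(),
    phase_velocity = raw$phase_velocity %||% list()
  )
  check_keys(cfg$grid, c(
    "depth_spacing", "lateral_spacing", "n_depth", "n_lateral",
    "frame_interval", "n_frames", "center_frequency", "sound_speed"
  ), "grid")
  check_keys(cfg$simulation, c(
    "speed_range", "snr_db", "amplitude", "use_iq", "push_time",
    "push_duration"
  ), "simulation")
  check_keys(cfg$motion, c("kernel_depth", "kernel_lateral", "kernel_time"),
    "motion")
  check_keys(cfg$group_velocity,
    c("n_iter", "residual_threshold", "min_samples"), "group_velocity")
  check_keys(cfg$phase_velocity,
    c("pad_factor", "v_min", "v_max", "prominence_threshold",
      "min_valid_fraction"), "phase_velocity")
  sim_defaults <- list(
    speed_range = c(2.5, 7.5), snr_db = 25, amplitude = 0.01,
    use_iq = TRUE, push_time = 1e-3, push_duration = 4e-4
  )
  cfg$simulation <- utils::modifyList(sim_defaults, cfg$simulation)
  stopifnot(
    cfg$n_plaques >= 1, cfg$acquisitions_per_plaque >= 1,
    length(cfg$simulation$speed_range) == 2,
    cfg$simulation$speed_range[1] > 0,
    diff(cfg$simulation$speed_range) >= 0
  )
  structure(cfg, class = "pipeline_config")
}

check_keys <- function(block, known, where) {
  unknown <- setdiff(names(block), known)
  if (length(unknown) > 0) {
    stop(sprintf(
      "unknown configuration key(s) in %s: %s", where,
      paste(unknown, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(TRUE)
}
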