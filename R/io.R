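#' Default run configuration
#'
#' Nested configuration covering the fuzzy intensity controller, the
#' speed-timing model, the synthetic plant, and the trial grid, with every
#' default embedded. Saved/loaded as YAML by [save_config()] /
#' [load_config()]; unknown keys in a file are rejected.
#'
#' @return Nested list of class \code{run_config}.
#' @export
default_config <- function() {
  plant <- unclass(plant_params())
  structure(list(
    seed = 1L,
    flc = list(
      theta_req = 4.9,
      e_universe = c(-10, 10),
      de_universe = c(-60, 60),
      output_peaks = c(0.15, 0.5, 0.85),
      defuzz_resolution = 1001L,
      amplitude_cap = 120,
      rule_orientation = "de_rows",
      rules = unname(apply(default_rules(), 1, paste, collapse = " "))),
    timing_model = list(
      interval_slope = -111.7, interval_intercept = 416.9,
      duration_slope = -213.2, duration_intercept = 877.7,
      speed_domain = c(0.2, 2.0)),
    plant = plant,
    trial = list(
      conditions = c("NS", "HOS", "SAS", "IDAS"),
      speeds = c("slow", "free", "fast"),
      free_speed = 1.0, speed_scale = 0.275, n_cycles = 30L,
      seeds = 1L, fixed_amplitude = NA, amplitude_cap = 120),
    stimulus = list(pulse_width_us = 390, frequency_hz = 40,
                    amplitude_max = 120)),
    class = "run_config")
}

check_known_keys <- function(x, ref, path = "") {
  extra <- setdiff(names(x), names(ref))
  if (length(extra))
    stop("unknown configuration key(s): ",
         paste0(path, extra, collapse = ", "))
  for (k in names(x)) {
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]])) && is.list(x[[k]]))
      check_known_keys(x[[k]], ref[[k]], paste0(path, k, "."))
  }
  invisible(NULL)
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && !is.null(names(base[[k]])) &&
        is.list(override[[k]])) {
      base[[k]] <- merge_config(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Load a YAML run configuration
#'
#' Reads the file, rejects unknown keys, and fills unspecified values from
#' [default_config()]. A saved configuration loads back identically.
#'
#' @param path YAML file path.
#' @return A \code{run_config}.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  ref <- default_config()
  check_known_keys(raw, ref)
  cfg <- merge_config(unclass(ref), raw)
  class(cfg) <- "run_config"
  cfg
}

#' Save a run configuration as YAML
#'
#' @param config A \code{run_config}.
#' @param path Output file path.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Build component objects from a run configuration
#'
#' @param config A \code{run_config}.
#' @name config_components
#' @export
config_flc <- function(config) {
  f <- config$flc
  rules <- do.call(rbind, lapply(f$rules, function(r) strsplit(r, " +")[[1]]))
  dimnames(rules) <- list(c("NB", "NM", "NES", "ZE", "PS", "PM", "PB"),
                          c("NB", "NM", "NES", "ZE", "PS", "PM", "PB"))
  flc_config(theta_req = f$theta_req, e_universe = f$e_universe,
             de_universe = f$de_universe, output_peaks = f$output_peaks,
             rules = rule_table(rules, f$rule_orientation),
             defuzz_resolution = f$defuzz_resolution,
             amplitude_cap = f$amplitude_cap)
}

#' @rdname config_components
#' @export
config_timing <- function(config) {
  t <- config$timing_model
  speed_timing_model(t$interval_slope, t$interval_intercept,
                     t$duration_slope, t$duration_intercept, t$speed_domain)
}

#' @rdname config_components
#' @export
config_plant <- function(config) {
  do.call(plant_params, config$plant)
}

#' Read a marker trajectory CSV
#'
#' Expected columns: \code{time} (s) then \code{<marker>_<x|y|z>} (m) for
#' thigh, knee, shank, ankle, toe. A missing column raises a schema error
#' naming it.
#'
#' @param path CSV path.
#' @return A [marker_trajectory()].
#' @export
read_marker_csv <- function(path) {
  marker_trajectory(utils::read.csv(path))
}

#' @rdname read_marker_csv
#' @param markers A [marker_trajectory()].
#' @export
write_marker_csv <- function(markers, path) {
  utils::write.csv(as.data.frame(markers), path, row.names = FALSE)
  invisible(path)
}

#' Read / write a footswitch CSV (columns time, pressed)
#'
#' @param path CSV path.
#' @export
read_footswitch_csv <- function(path) {
  footswitch_trace(utils::read.csv(path))
}

#' @rdname read_footswitch_csv
#' @param fs A [footswitch_trace()].
#' @export
write_footswitch_csv <- function(fs, path) {
  utils::write.csv(as.data.frame(fs), path, row.names = FALSE)
  invisible(path)
}

#' Offline analysis of a recorded trial
#'
#' The full measurement pipeline on marker + footswitch files: joint
#' angles, zero-phase low-pass filtering, gait events, per-cycle metrics
#' and step speeds.
#'
#' @param markers A [marker_trajectory()].
#' @param fs A [footswitch_trace()].
#' @param cutoff_hz Filter cutoff, Hz.
#' @param toe_lift_threshold Toe-off detection threshold, m.
#' @return Per-cycle data frame: events, \code{theta_a},
#'   \code{pf_at_toe_off}, \code{max_knee_flexion}, \code{step_speed},
#'   \code{n_s}.
#' @export
analyze_trial <- function(markers, fs, cutoff_hz = 15,
                          toe_lift_threshold = 0.005) {
  events <- detect_gait_events(fs, markers,
                               toe_lift_threshold = toe_lift_threshold)
  angles <- filter_angles(compute_joint_angles(markers), cutoff_hz)
  met <- compute_gait_metrics(angles, events)
  spd <- estimate_speed(markers$toe_z, markers$time, events)
  out <- merge(events, met, by = "cycle")
  out <- merge(out, stats::setNames(spd, c("cycle", "step_speed", "n_s")),
               by = "cycle", all.x = TRUE)
  out[order(out$cycle), ]
}

#' Write per-cycle metrics to CSV
#'
#' @param metrics Data frame from [analyze_trial()] or a trial's
#'   \code{cycles} table.
#' @param path Output CSV path.
#' @export
write_metrics_csv <- function(metrics, path) {
  utils::write.csv(as.data.frame(metrics), path, row.names = FALSE)
  invisible(path)
}
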