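#' Trial configuration
#'
#' One treadmill trial: a stimulation condition at a walking speed. The
#' four conditions are NS (no stimulation), HOS (fixed intensity,
#' heel-off to heel-strike window), SAS (fixed intensity, speed-adaptive
#' onset and duration) and IDAS (fuzzy-adaptive intensity with SAS
#' timing). Fast and slow speeds scale the free speed by
#' \code{1 +/- speed_scale}.
#'
#' @param condition One of \code{"NS"}, \code{"HOS"}, \code{"SAS"},
#'   \code{"IDAS"}.
#' @param speed_label \code{"slow"}, \code{"free"} or \code{"fast"}.
#' @param free_speed Free (comfortable) belt speed, m/s.
#' @param speed_scale Fast/slow proportion (default 0.275, the middle of
#'   the 25-30% protocol band).
#' @param n_cycles Gait cycles to simulate.
#' @param seed RNG seed for the trial.
#' @param fixed_amplitude HOS/SAS intensity, mA; \code{NULL} = calibrate
#'   statically to a neutral (0 deg) seated ankle angle.
#' @param amplitude_cap IDAS intensity cap (tolerance cap), mA.
#' @param initial_speed Speed used for the stimulation window before any
#'   step speed has been measured; defaults to the commanded belt speed
#'   (known to the operator who set the treadmill).
#' @return Object of class \code{trial_config}.
#' @export
trial_config <- function(condition = c("IDAS", "NS", "HOS", "SAS"),
                         speed_label = c("free", "slow", "fast"),
                         free_speed = 1.0, speed_scale = 0.275,
                         n_cycles = 30, seed = 1,
                         fixed_amplitude = NULL, amplitude_cap = 120,
                         initial_speed = NULL) {
  condition <- match.arg(condition)
  speed_label <- match.arg(speed_label)
  stopifnot(n_cycles >= 1, speed_scale >= 0, speed_scale < 1)
  speed <- switch(speed_label,
                  slow = free_speed * (1 - speed_scale),
                  free = free_speed,
                  fast = free_speed * (1 + speed_scale))
  structure(list(condition = condition, speed_label = speed_label,
                 free_speed = free_speed, speed_scale = speed_scale,
                 speed = speed, n_cycles = as.integer(n_cycles),
                 seed = seed, fixed_amplitude = fixed_amplitude,
                 amplitude_cap = amplitude_cap,
                 initial_speed = if (is.null(initial_speed)) speed
                                 else initial_speed),
            class = "trial_config")
}

#' Calibrate a fixed stimulation intensity statically
#'
#' Smallest amplitude (on a \code{step} mA grid) whose static seated
#' response reaches \code{target} degrees, mirroring the clinical
#' procedure of raising the intensity until the seated ankle reaches a
#' neutral angle. Returns the maximum with a warning when the target is
#' unreachable.
#'
#' @param params A [plant_params()].
#' @param target Target static ankle angle, deg (default 0, neutral).
#' @param step Amplitude grid, mA.
#' @param max_amplitude Search limit, mA.
#' @export
calibrate_static_amplitude <- function(params = plant_params(), target = 0,
                                       step = 0.5, max_amplitude = 120) {
  grid <- seq(0, max_amplitude, by = step)
  ok <- static_response(grid, params) >= target
  if (!any(ok)) {
    warning("static target ", target, " deg unreachable below ",
            max_amplitude, " mA; using the maximum")
    return(max_amplitude)
  }
  grid[which(ok)[1]]
}

#' IDAS intensity cap
#'
#' The cap is the configured tolerance cap, or - if smaller - the smallest
#' amplitude whose static response reaches \code{theta_req + 2} degrees
#' ("sufficient dorsiflexion"), whichever binds first.
#'
#' @param params A [plant_params()].
#' @param tolerance_cap Configured tolerance cap, mA.
#' @param theta_req Reference dorsiflexion, deg.
#' @export
idas_amplitude_cap <- function(params = plant_params(), tolerance_cap = 120,
                               theta_req = 4.9) {
  grid <- seq(0, tolerance_cap, by = 0.5)
  ok <- static_response(grid, params) >= theta_req + 2
  if (any(ok)) min(tolerance_cap, grid[which(ok)[1]]) else tolerance_cap
}

# measured per-cycle processing: footswitch heel-off, kinematic toe-off,
# filtered angles, swing metrics and raw step speed
measure_cycle <- function(sim, markers, params,
                          toe_lift_threshold = 0.005, cutoff_hz = 15) {
  t0 <- sim$time[1]
  t_end <- t0 + sim$duration
  fsw <- generate_footswitch(sim$events, sim$time)
  i_off <- which(fsw$pressed == 0)[1]
  heel_off <- if (is.na(i_off)) NA_real_ else fsw$time[i_off]
  stance <- fsw$pressed == 1
  toe_off <- NA_real_
  if (!is.na(heel_off) && any(stance)) {
    lift <- stats::median(markers$toe_y[stance]) + toe_lift_threshold
    j <- which(markers$time > heel_off & markers$toe_y > lift)
    if (length(j)) toe_off <- markers$time[j[1]]
  }
  if (is.na(toe_off)) return(NULL)
  ev <- data.frame(cycle = 1L, start_time = t0, heel_off = heel_off,
                   toe_off = toe_off, heel_strike = t_end)
  class(ev) <- c("gait_event_table", class(ev))
  angles <- filter_angles(compute_joint_angles(markers), cutoff_hz)
  met <- suppressWarnings(compute_gait_metrics(angles, ev))
  if (nrow(met) == 0) return(NULL)
  i0 <- which.min(abs(markers$time - t0))
  i1 <- which.min(abs(markers$time - toe_off))
  raw_speed <- abs(markers$toe_z[i1] - markers$toe_z[i0]) /
    (markers$time[i1] - markers$time[i0])
  list(events = ev, metrics = met, raw_speed = raw_speed)
}

#' Run one closed-loop treadmill trial
#'
#' Wires plant, measurement pipeline, timing model and (for IDAS) the fuzzy
#' intensity controller cycle by cycle. Every cycle: the step speed is
#' estimated from the measured toe trajectory and smoothed over the last
#' five steps; the condition's stimulation window is built; the stimulus is
#' delivered to the plant; the maximum swing dorsiflexion is measured from
#' the simulated marker data (not the ground truth); and, in IDAS only, the
#' fuzzy controller updates the intensity for the next cycle.
#'
#' An unreachable setpoint does not raise an error: the trial completes and
#' non-convergence shows as \code{NA} in [convergence_time()].
#'
#' @param config A [trial_config()].
#' @param plant A [plant_params()].
#' @param flc An [flc_config()] (IDAS only).
#' @param timing A [speed_timing_model()].
#' @param keep_recording Keep full marker/footswitch traces in the result.
#' @return Object of class \code{fes_trial}: \code{cycles} (per-cycle data
#'   frame with commanded amplitude, duty, error, metrics and speeds),
#'   \code{config}, and optionally \code{recording}.
#' @export
run_trial <- function(config, plant = plant_params(), flc = flc_config(),
                      timing = speed_timing_model(), keep_recording = FALSE) {
  stopifnot(inherits(config, "trial_config"))
  set.seed(config$seed)
  v <- config$speed
  fixed_amp <- if (config$condition %in% c("HOS", "SAS")) {
    if (is.null(config$fixed_amplitude))
      calibrate_static_amplitude(plant) else config$fixed_amplitude
  } else 0
  if (config$condition == "IDAS") {
    cap <- idas_amplitude_cap(plant, config$amplitude_cap, flc$theta_req)
    flc$amplitude_cap <- cap
    state <- flc_state(flc)
  }
  raws <- numeric(0)
  n_s <- config$initial_speed
  t0 <- 0; a0 <- 0
  rows <- list()
  rec_markers <- list(); rec_fsw <- list(); rec_events <- list()
  for (k in seq_len(config$n_cycles)) {
    T <- plant$cycle_intercept + plant$cycle_slope * v
    ho <- t0 + plant$heel_off_fraction * T
    hs <- t0 + T
    window <- switch(config$condition,
      NS = NULL,
      HOS = hos_window(ho, hs),
      SAS = build_window(ho, hs, n_s, timing),
      IDAS = build_window(ho, hs, n_s, timing))
    amplitude <- switch(config$condition,
      NS = 0, HOS = fixed_amp, SAS = fixed_amp, IDAS = state$amplitude)
    sim <- simulate_cycle(v, amplitude, window, plant, t0, a0)
    markers <- forward_kinematics(sim$angles, plant, v, sim$phase)
    meas <- measure_cycle(sim, markers, plant)
    theta_a <- NA_real_
    if (!is.null(meas)) {
      theta_a <- meas$metrics$theta_a
      raws <- c(raws, meas$raw_speed)
      recent <- raws[max(1, length(raws) - 4):length(raws)]
      n_s <- mean(recent)
    }
    duty <- NA_real_; de <- NA_real_
    if (config$condition == "IDAS") {
      prev_e <- state$e
      state <- update_intensity(state, theta_a, flc)
      duty <- state$duty; de <- state$de
    }
    rows[[k]] <- data.frame(
      cycle = k, t_start = t0, duration = sim$duration,
      condition = config$condition, speed_label = config$speed_label,
      commanded_speed = v, amplitude = amplitude,
      duty = duty,
      theta_a = theta_a,
      e = flc$theta_req - theta_a, de = de,
      pf_at_toe_off = if (is.null(meas)) NA_real_ else meas$metrics$pf_at_toe_off,
      max_knee_flexion = if (is.null(meas)) NA_real_ else meas$metrics$max_knee_flexion,
      raw_speed = if (is.null(meas)) NA_real_ else meas$raw_speed,
      n_s = n_s,
      stim_onset = if (is.null(window) || window$empty) NA_real_ else window$onset,
      stim_offset = if (is.null(window) || window$empty) NA_real_ else window$offset)
    if (keep_recording) {
      rec_markers[[k]] <- markers
      rec_fsw[[k]] <- generate_footswitch(sim$events, sim$time)
      rec_events[[k]] <- sim$events
    }
    t0 <- t0 + sim$duration
    a0 <- sim$a_end
  }
  out <- list(cycles = do.call(rbind, rows), config = config,
              plant = plant, flc = flc, timing = timing)
  if (keep_recording) {
    ev <- do.call(rbind, rec_events)
    ev$cycle <- seq_len(nrow(ev))
    out$recording <- list(
      markers = do.call(rbind, rec_markers),
      footswitch = do.call(rbind, rec_fsw),
      events = ev)
  }
  class(out) <- "fes_trial"
  out
}

#' Convergence time of the intensity loop
#'
#' Time from walking onset to the start of the first cycle whose absolute
#' dorsiflexion error is below \code{tol} and which is followed only by
#' cycles also satisfying the bound. \code{NA} when the trial never
#' converges.
#'
#' @param cycles Per-cycle data frame from [run_trial()].
#' @param tol Error bound, deg (default 2).
#' @return Time in seconds, or \code{NA}.
#' @export
convergence_time <- function(cycles, tol = 2) {
  ok <- abs(cycles$e) < tol
  ok[is.na(ok)] <- FALSE
  settled <- rev(cumprod(rev(ok))) == 1
  i <- which(settled)[1]
  if (is.na(i)) NA_real_ else cycles$t_start[i]
}

#' Run the full condition-by-speed experiment grid
#'
#' @param conditions,speeds Conditions and speed labels to cross.
#' @param seeds One trial per seed per cell.
#' @param free_speed,n_cycles,... Passed to [trial_config()].
#' @param plant,flc,timing Shared component configurations.
#' @return List of \code{fes_trial} objects (class
#'   \code{fes_experiment}).
#' @export
run_experiment <- function(conditions = c("NS", "HOS", "SAS", "IDAS"),
                           speeds = c("slow", "free", "fast"),
                           seeds = 1, free_speed = 1.0, n_cycles = 30,
                           plant = plant_params(), flc = flc_config(),
                           timing = speed_timing_model(), ...) {
  trials <- list()
  for (cond in conditions) for (sp in speeds) for (s in seeds) {
    cfg <- trial_config(condition = cond, speed_label = sp,
                        free_speed = free_speed, n_cycles = n_cycles,
                        seed = s, ...)
    trials[[length(trials) + 1]] <- run_trial(cfg, plant, flc, timing)
  }
  class(trials) <- "fes_experiment"
  trials
}

#' Summarise trials into condition-by-speed outcome tables
#'
#' Mean and SD of the maximum swing dorsiflexion, plantar flexion at
#' toe-off and maximum swing knee flexion, plus the mean absolute
#' dorsiflexion error and the convergence time, per condition and speed
#' (pooling cycles over seeds).
#'
#' @param trials A \code{fes_experiment} or list of \code{fes_trial}.
#' @param tol Convergence bound passed to [convergence_time()].
#' @return Data frame, one row per condition x speed.
#' @export
summarize_trials <- function(trials, tol = 2) {
  if (inherits(trials, "fes_trial")) trials <- list(trials)
  cyc <- do.call(rbind, lapply(trials, function(tr) tr$cycles))
  conv <- do.call(rbind, lapply(trials, function(tr) {
    data.frame(condition = tr$config$condition,
               speed_label = tr$config$speed_label,
               conv = convergence_time(tr$cycles, tol))
  }))
  cells <- unique(cyc[c("condition", "speed_label")])
  out <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- cyc$condition == cells$condition[i] &
      cyc$speed_label == cells$speed_label[i]
    d <- cyc[sel & !is.na(cyc$theta_a), ]
    if (nrow(d) == 0) {
      warning("empty cell ", cells$condition[i], "/", cells$speed_label[i])
      next
    }
    cv <- conv$conv[conv$condition == cells$condition[i] &
                      conv$speed_label == cells$speed_label[i]]
    sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)
    out[[i]] <- data.frame(
      condition = cells$condition[i], speed_label = cells$speed_label[i],
      n = nrow(d),
      theta_a_mean = mean(d$theta_a), theta_a_sd = sd0(d$theta_a),
      pf_mean = mean(d$pf_at_toe_off), pf_sd = sd0(d$pf_at_toe_off),
      knee_mean = mean(d$max_knee_flexion), knee_sd = sd0(d$max_knee_flexion),
      mean_abs_error = mean(abs(d$e)),
      convergence_time = if (all(is.na(cv))) NA_real_ else
        max(cv, na.rm = TRUE))
  }
  do.call(rbind, out)
}
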