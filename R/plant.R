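#' Synthetic hemiparetic treadmill-walking subject
#'
#' Parameter set for the simulated plant: a dropfoot gait pattern whose
#' unstimulated swing dorsiflexion peaks well below the healthy reference,
#' a monotone saturating recruitment curve mapping pulse amplitude to
#' tibialis anterior activation, first-order activation dynamics, and a
#' four-segment sagittal kinematic chain rendered as marker trajectories.
#'
#' The recruitment curve is \code{tanh(((A - threshold) / scale)^shape)}
#' (zero at and below threshold): a steep rise just above the motor
#' threshold followed by a long, gentle shoulder. With the defaults the
#' muscle does not saturate within the 0-120 mA stimulator range, as is
#' common for surface stimulation of a paretic dorsiflexor; the derived
#' amplitude at any recruitment level is given by
#' [recruitment_saturation()].
#'
#' @param swing_dorsiflexion_peak Unstimulated maximum swing dorsiflexion,
#'   deg (default 0.7, a marked dropfoot).
#' @param pf_at_toe_off Unstimulated ankle angle at toe-off, deg.
#' @param knee_peak Maximum swing knee flexion, deg.
#' @param stance_fraction,heel_off_fraction Gait-cycle phase fractions of
#'   toe-off and heel-off.
#' @param cycle_intercept,cycle_slope Cycle duration model
#'   \code{T = cycle_intercept + cycle_slope * v} (s, s per m/s).
#' @param recruitment_threshold,recruitment_scale,recruitment_shape
#'   Recruitment curve parameters (mA, mA, dimensionless).
#' @param tau_act,tau_deact Activation rise and decay time constants, s.
#' @param max_added_dorsiflexion Dorsiflexion added at full activation, deg
#'   (the plant "gain").
#' @param rest_angle Seated resting ankle angle, deg (used for static
#'   intensity calibration).
#' @param knee_coupling Fraction of the stimulation effect coupled into the
#'   knee trace (default 0).
#' @param effect_onset_phase,effect_ramp Phase gate of the stimulation
#'   effect: zero before onset, cosine ramp to one over \code{effect_ramp}.
#' @param thigh_length,shank_length,foot_length Segment lengths, m
#'   (marker-to-marker; foot = lateral malleolus to metatarsal marker).
#' @param thigh_swing_deg Amplitude of the sinusoidal thigh inclination
#'   profile, deg.
#' @param noise_sd Cycle-to-cycle trajectory variability: an angle offset
#'   drawn once per cycle, deg.
#' @param sensor_noise_sd White measurement noise on the angle traces, deg.
#' @param toe_lift_height,toe_lift_exponent Swing toe clearance profile
#'   \code{height * sin(pi u)^exponent}, m.
#' @param toe_z_front Anterior toe position at heel-strike, m.
#' @param lateral_x Mediolateral marker offset, m.
#' @param sample_rate Hz.
#' @param speed_domain Supported belt speeds, m/s.
#' @return Object of class \code{plant_params}.
#' @export
plant_params <- function(swing_dorsiflexion_peak = 0.7,
                         pf_at_toe_off = -4.9,
                         knee_peak = 33,
                         stance_fraction = 0.62,
                         heel_off_fraction = 0.40,
                         cycle_intercept = 1.4,
                         cycle_slope = -0.3,
                         recruitment_threshold = 5,
                         recruitment_scale = 200,
                         recruitment_shape = 0.5,
                         tau_act = 0.05,
                         tau_deact = 0.08,
                         max_added_dorsiflexion = 12,
                         rest_angle = -4,
                         knee_coupling = 0,
                         effect_onset_phase = 0.55,
                         effect_ramp = 0.10,
                         thigh_length = 0.42,
                         shank_length = 0.43,
                         foot_length = 0.19,
                         thigh_swing_deg = 20,
                         noise_sd = 0.2,
                         sensor_noise_sd = 0.05,
                         toe_lift_height = 0.05,
                         toe_lift_exponent = 0.7,
                         toe_z_front = 0.15,
                         lateral_x = 0.10,
                         sample_rate = 100,
                         speed_domain = c(0.2, 2.0)) {
  stopifnot(stance_fraction > 0, stance_fraction < 1,
            heel_off_fraction > 0, heel_off_fraction < stance_fraction,
            noise_sd >= 0, sensor_noise_sd >= 0,
            tau_act > 0, tau_deact > 0,
            recruitment_scale > 0, recruitment_shape > 0,
            all(c(thigh_length, shank_length, foot_length) > 0))
  p <- as.list(environment())
  if (p$swing_dorsiflexion_peak + p$max_added_dorsiflexion <= 4.9)
    warning("setpoint unreachable: baseline peak + max added dorsiflexion ",
            "does not exceed 4.9 degrees; closed-loop trials will not converge")
  structure(p, class = "plant_params")
}

#' Recruitment curve
#'
#' Monotone saturating map from pulse amplitude to the activated fraction
#' of the muscle: zero at and below the motor threshold, rising as
#' \code{tanh(((A - threshold)/scale)^shape)} towards one.
#'
#' @param amplitude Pulse amplitude, mA (vectorised).
#' @param params A [plant_params()].
#' @return Activation level(s) in \[0, 1\].
#' @export
recruitment <- function(amplitude, params = plant_params()) {
  stopifnot(all(amplitude >= 0))
  s <- pmax(0, (amplitude - params$recruitment_threshold) /
              params$recruitment_scale)
  tanh(s^params$recruitment_shape)
}

#' Amplitude reaching a given recruitment level
#'
#' @param params A [plant_params()].
#' @param level Recruitment level in (0, 1); default 0.95 ("saturation").
#' @return Amplitude, mA.
#' @export
recruitment_saturation <- function(params = plant_params(), level = 0.95) {
  stopifnot(level > 0, level < 1)
  params$recruitment_threshold +
    params$recruitment_scale * atanh(level)^(1 / params$recruitment_shape)
}

#' Static (seated) ankle response to stimulation
#'
#' Steady-state ankle angle with the subject seated: the resting angle plus
#' the full recruitment-scaled dorsiflexion gain. Used to calibrate fixed
#' stimulation intensities against a target posture.
#'
#' @inheritParams recruitment
#' @export
static_response <- function(amplitude, params = plant_params()) {
  params$rest_angle + params$max_added_dorsiflexion *
    recruitment(amplitude, params)
}

#' First-order activation dynamics
#'
#' Activation rises towards the recruitment level with time constant
#' \code{tau_act} while the trigger \code{u_out2} is high and decays with
#' \code{tau_deact} while low, integrated exactly per sample.
#'
#' @param amplitude Pulse amplitude, mA.
#' @param window A \code{stim_window} (or \code{NULL} for no stimulation).
#' @param time Sample times, s.
#' @param params A [plant_params()].
#' @param a0 Initial activation.
#' @return List with \code{activation} (series in \[0, 1\]) and
#'   \code{u_out2} (0/1 trigger series).
#' @export
activation_dynamics <- function(amplitude, window, time,
                                params = plant_params(), a0 = 0) {
  u <- if (is.null(window)) integer(length(time)) else
    render_trigger(window, time)
  target <- recruitment(amplitude, params) * u
  n <- length(time)
  a <- numeric(n)
  a[1] <- a0
  dt <- if (n > 1) stats::median(diff(time)) else 1 / params$sample_rate
  for (i in seq_len(n)[-1]) {
    tau <- if (u[i] == 1) params$tau_act else params$tau_deact
    a[i] <- target[i] + (a[i - 1] - target[i]) * exp(-dt / tau)
  }
  list(activation = a, u_out2 = u)
}

# smooth key-point interpolation: half-cosine easing between control points
profile_interp <- function(phase, pts) {
  v <- numeric(length(phase))
  for (i in seq_len(nrow(pts) - 1)) {
    lo <- pts$phase[i]; hi <- pts$phase[i + 1]
    in_seg <- phase >= lo & phase <= hi
    u <- (phase[in_seg] - lo) / (hi - lo)
    v[in_seg] <- pts$value[i] +
      (pts$value[i + 1] - pts$value[i]) * (1 - cos(pi * u)) / 2
  }
  v
}

#' Baseline (unstimulated) ankle angle profile
#'
#' Smooth piecewise-cosine dropfoot profile over one gait cycle: mild
#' plantar flexion after heel-strike, tibial progression in stance, the
#' configured plantar flexion at toe-off, and a swing dorsiflexion peak at
#' 80% of the cycle equal to \code{swing_dorsiflexion_peak}.
#'
#' @param phase Gait-cycle phase in \[0, 1\].
#' @param params A [plant_params()].
#' @export
baseline_ankle <- function(phase, params = plant_params()) {
  pts <- data.frame(
    phase = c(0, 0.12, params$heel_off_fraction, params$stance_fraction,
              0.80, 1),
    value = c(-1.5, -3.5, 1.0, params$pf_at_toe_off,
              params$swing_dorsiflexion_peak, -1.5))
  profile_interp(phase, pts)
}

#' Baseline knee flexion profile
#'
#' @inheritParams baseline_ankle
#' @export
baseline_knee <- function(phase, params = plant_params()) {
  pts <- data.frame(
    phase = c(0, 0.12, params$heel_off_fraction, params$stance_fraction,
              0.75, 1),
    value = c(5, 15, 8, 25, params$knee_peak, 5))
  profile_interp(phase, pts)
}

# phase gate confining the stimulation effect to late stance and swing
effect_gate <- function(phase, params) {
  u <- (phase - params$effect_onset_phase) / params$effect_ramp
  ifelse(u <= 0, 0, ifelse(u >= 1, 1, (1 - cos(pi * u)) / 2))
}

#' Simulate one gait cycle of the synthetic subject
#'
#' Generates the cycle's time base, ground-truth events (at the configured
#' phase fractions), and ankle/knee angle traces: the baseline profile plus
#' the stimulation effect \code{max_added_dorsiflexion * a(t) * g(phase)},
#' where \code{a} follows [activation_dynamics()] and \code{g} confines the
#' effect to late stance and swing. Noise (a per-cycle offset plus white
#' measurement noise) is added to the returned \code{angles}; the
#' noise-free traces are in \code{angles_true}. Randomness comes from the
#' current R RNG state; seed it for reproducibility.
#'
#' @param v Belt speed, m/s.
#' @param amplitude Pulse amplitude, mA (0 = no stimulation).
#' @param window A \code{stim_window} in trial time, or \code{NULL}.
#' @param params A [plant_params()].
#' @param t0 Cycle start time, s.
#' @param a0 Activation carried in from the previous cycle.
#' @param noise Logical; add noise to the measured angle traces.
#' @return List: \code{time}, \code{phase}, \code{angles},
#'   \code{angles_true} (both \code{joint_angle_trace}), \code{events}
#'   (one-row data frame), \code{activation}, \code{u_out2},
#'   \code{duration}, \code{a_end}.
#' @export
simulate_cycle <- function(v, amplitude = 0, window = NULL,
                           params = plant_params(), t0 = 0, a0 = 0,
                           noise = TRUE) {
  if (v < params$speed_domain[1] || v > params$speed_domain[2])
    stop("belt speed ", v, " outside plant domain")
  # cycle duration snapped to the sample grid so multi-cycle trials stay
  # uniformly sampled
  n <- round((params$cycle_intercept + params$cycle_slope * v) *
               params$sample_rate)
  T <- n / params$sample_rate
  time <- t0 + (0:(n - 1)) / params$sample_rate
  phase <- (time - t0) / T
  act <- activation_dynamics(amplitude, window, time, params, a0)
  added <- params$max_added_dorsiflexion * act$activation *
    effect_gate(phase, params)
  ankle_true <- baseline_ankle(phase, params) + added
  knee_true <- baseline_knee(phase, params) + params$knee_coupling * added
  ankle <- ankle_true
  knee <- knee_true
  if (noise) {
    ankle <- ankle + stats::rnorm(1, 0, params$noise_sd) +
      stats::rnorm(n, 0, params$sensor_noise_sd)
    knee <- knee + stats::rnorm(1, 0, params$noise_sd) +
      stats::rnorm(n, 0, params$sensor_noise_sd)
  }
  mk_trace <- function(a, k) {
    d <- data.frame(time = time, ankle_angle = a, knee_angle = k)
    class(d) <- c("joint_angle_trace", class(d))
    d
  }
  events <- data.frame(cycle = 1L, start_time = t0,
                       heel_off = t0 + params$heel_off_fraction * T,
                       toe_off = t0 + params$stance_fraction * T,
                       heel_strike = t0 + T)
  class(events) <- c("gait_event_table", class(events))
  list(time = time, phase = phase,
       angles = mk_trace(ankle, knee),
       angles_true = mk_trace(ankle_true, knee_true),
       events = events, activation = act$activation, u_out2 = act$u_out2,
       duration = T, a_end = act$activation[n])
}

rot_sagittal <- function(m, deg) {
  a <- deg * pi / 180
  cbind(m[, 1] * cos(a) - m[, 2] * sin(a),
        m[, 1] * sin(a) + m[, 2] * cos(a))
}

#' Forward kinematics: joint angles to marker trajectories
#'
#' Renders the four-segment sagittal chain as the five marker positions.
#' The chain is anchored at the toe: during stance the toe is planted on
#' the belt and translates posteriorly at the belt speed; during swing it
#' follows a smooth clearance path returning to the anterior contact
#' position. The thigh inclination follows a sinusoidal profile over the
#' cycle, so the (emergent) hip trajectory oscillates vertically. Inverse
#' of [compute_joint_angles()] up to the shared sign conventions.
#'
#' @param angles A \code{joint_angle_trace} spanning one cycle.
#' @param params A [plant_params()].
#' @param v Belt speed, m/s.
#' @param phase Gait-cycle phase per sample; default a single uniform cycle.
#' @return A [marker_trajectory()].
#' @export
forward_kinematics <- function(angles, params = plant_params(), v = 1,
                               phase = NULL) {
  n <- nrow(angles)
  if (is.null(phase)) phase <- (seq_len(n) - 1) / n
  th <- params$thigh_swing_deg * cos(2 * pi * phase)
  u_t <- cbind(sin(th * pi / 180), -cos(th * pi / 180))  # (z, y), distal
  u_s <- rot_sagittal(u_t, -angles$knee_angle)
  u_f <- rot_sagittal(u_s, 90 + angles$ankle_angle)
  # toe path
  sf <- params$stance_fraction
  t_rel <- (angles$time - angles$time[1])
  T <- if (n > 1) (angles$time[2] - angles$time[1]) * n else 1
  z_end <- params$toe_z_front - v * sf * T
  toe_z <- ifelse(phase <= sf,
                  params$toe_z_front - v * t_rel,
                  NA_real_)
  sw <- phase > sf
  u <- (phase[sw] - sf) / (1 - sf)
  toe_z[sw] <- z_end + (params$toe_z_front - z_end) * (1 - cos(pi * u)) / 2
  toe_y <- numeric(n)
  toe_y[sw] <- params$toe_lift_height * sin(pi * u)^params$toe_lift_exponent
  toe <- cbind(toe_z, toe_y)
  ankle <- toe - params$foot_length * u_f
  knee <- ankle - params$shank_length * u_s
  shank <- knee + 0.5 * params$shank_length * u_s
  thigh <- knee - 0.5 * params$thigh_length * u_t
  df <- data.frame(time = angles$time)
  pos <- list(thigh = thigh, knee = knee, shank = shank, ankle = ankle,
              toe = toe)
  for (m in names(pos)) {
    df[[paste0(m, "_x")]] <- params$lateral_x
    df[[paste0(m, "_y")]] <- pos[[m]][, 2]
    df[[paste0(m, "_z")]] <- pos[[m]][, 1]
  }
  marker_trajectory(df)
}

#' Footswitch trace from ground-truth events
#'
#' Pressed (1) from each cycle's heel-strike to its heel-off, 0 otherwise.
#'
#' @param events A \code{gait_event_table}.
#' @param time Sample times, s.
#' @return A [footswitch_trace()].
#' @export
generate_footswitch <- function(events, time) {
  pressed <- integer(length(time))
  for (i in seq_len(nrow(events))) {
    pressed[time >= events$start_time[i] & time < events$heel_off[i]] <- 1L
  }
  footswitch_trace(data.frame(time = time, pressed = pressed))
}
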