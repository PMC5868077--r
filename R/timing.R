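#' Speed-to-timing model for stimulation onset and duration
#'
#' Two linear relations map smoothed walking speed (m/s) to (i) the time
#' interval from the heel-off event to tibialis anterior stimulation onset
#' and (ii) the stimulation duration, both in milliseconds. The default
#' coefficients are the values fitted on healthy-subject EMG in the
#' preliminary experiment behind this controller design; both slopes are
#' negative, so faster walking means earlier onset after heel-off and a
#' shorter burst.
#'
#' @param interval_slope,interval_intercept Onset-interval line, ms per
#'   (m/s) and ms. Defaults -111.7 and 416.9.
#' @param duration_slope,duration_intercept Duration line. Defaults -213.2
#'   and 877.7.
#' @param speed_domain Speeds (m/s) over which the linear fits are trusted;
#'   outside it the speed is clamped with a warning.
#' @return Object of class \code{speed_timing_model}.
#' @export
speed_timing_model <- function(interval_slope = -111.7,
                               interval_intercept = 416.9,
                               duration_slope = -213.2,
                               duration_intercept = 877.7,
                               speed_domain = c(0.2, 2.0)) {
  stopifnot(length(speed_domain) == 2, speed_domain[1] < speed_domain[2],
            speed_domain[1] > 0)
  structure(list(interval_slope = interval_slope,
                 interval_intercept = interval_intercept,
                 duration_slope = duration_slope,
                 duration_intercept = duration_intercept,
                 speed_domain = speed_domain),
            class = "speed_timing_model")
}

clamp_speed <- function(v, model) {
  if (v <= 0) stop("walking speed must be positive")
  if (v < model$speed_domain[1] || v > model$speed_domain[2]) {
    warning(sprintf("speed %.3f m/s outside model domain [%g, %g]; clamped",
                    v, model$speed_domain[1], model$speed_domain[2]))
    v <- min(max(v, model$speed_domain[1]), model$speed_domain[2])
  }
  v
}

#' Heel-off to stimulation-onset interval
#'
#' @param v Walking speed, m/s (> 0; clamped to the model's speed domain).
#' @param model A [speed_timing_model()].
#' @return Interval in ms, clamped at zero.
#' @export
time_interval <- function(v, model = speed_timing_model()) {
  v <- clamp_speed(v, model)
  max(0, model$interval_slope * v + model$interval_intercept)
}

#' Stimulation duration
#'
#' @inheritParams time_interval
#' @return Duration in ms, clamped at zero.
#' @export
stim_duration <- function(v, model = speed_timing_model()) {
  v <- clamp_speed(v, model)
  max(0, model$duration_slope * v + model$duration_intercept)
}

#' Speed-adaptive stimulation window for one gait cycle
#'
#' Onset is \code{heel_off + time_interval(v)}, offset
#' \code{onset + stim_duration(v)}, truncated at the next heel-strike. If
#' the onset itself falls at or beyond the next heel-strike the window is
#' empty and stimulation is skipped for the cycle (with a warning).
#'
#' @param heel_off,next_heel_strike Event times, s.
#' @param v Smoothed walking speed, m/s.
#' @param model A [speed_timing_model()].
#' @return Object of class \code{stim_window}: \code{onset}, \code{offset}
#'   (s) and \code{empty} flag. \code{u_out2} is rendered from it by
#'   [render_trigger()].
#' @export
build_window <- function(heel_off, next_heel_strike, v,
                         model = speed_timing_model()) {
  stopifnot(heel_off < next_heel_strike)
  onset <- heel_off + time_interval(v, model) / 1000
  if (onset >= next_heel_strike) {
    warning("stimulation onset after next heel-strike; cycle skipped")
    return(structure(list(onset = onset, offset = onset, empty = TRUE),
                     class = "stim_window"))
  }
  offset <- min(onset + stim_duration(v, model) / 1000, next_heel_strike)
  structure(list(onset = onset, offset = offset, empty = FALSE),
            class = "stim_window")
}

#' Heel-off-triggered window (HOS condition)
#'
#' Stimulation runs from heel-off to the following heel-strike, the classic
#' footswitch-triggered scheme.
#'
#' @param heel_off,heel_strike Event times, s.
#' @export
hos_window <- function(heel_off, heel_strike) {
  if (!(heel_off < heel_strike)) stop("heel_off must precede heel_strike")
  structure(list(onset = heel_off, offset = heel_strike, empty = FALSE),
            class = "stim_window")
}

#' Render the binary trigger trace u_out2
#'
#' 1 on samples in \code{[onset, offset)}, 0 elsewhere (right-open).
#'
#' @param window A \code{stim_window}.
#' @param time Sample times, s.
#' @return Integer 0/1 vector along \code{time}.
#' @export
render_trigger <- function(window, time) {
  if (window$empty) return(integer(length(time)))
  as.integer(time >= window$onset & time < window$offset)
}
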