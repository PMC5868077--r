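MARKERS <- c("thigh", "knee", "shank", "ankle", "toe")

marker_cols <- function() {
  as.vector(t(outer(MARKERS, c("x", "y", "z"), paste, sep = "_")))
}

check_uniform_time <- function(time, tol = 1e-9) {
  if (length(time) < 2) return(invisible(NULL))
  dt <- diff(time)
  if (any(dt <= 0)) stop("time must be strictly increasing")
  if (max(dt) - min(dt) > tol)
    stop("non-uniform sampling: time steps differ by more than ", tol, " s")
  invisible(NULL)
}

#' Marker trajectory container
#'
#' Five lower-limb markers (mid-thigh, lateral knee, mid-shank, lateral
#' malleolus = "ankle", 2nd-3rd metatarsal space = "toe"), each with
#' coordinates x (mediolateral), y (vertical) and z (anterior-posterior,
#' anterior positive), in metres, uniformly sampled.
#'
#' @param df Data frame with column \code{time} (s) and columns
#'   \code{<marker>_<x|y|z>} for the five markers.
#' @return The data frame with class \code{marker_trajectory}.
#' @export
marker_trajectory <- function(df) {
  need <- c("time", marker_cols())
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("marker trajectory missing column(s): ", paste(miss, collapse = ", "))
  if (anyNA(df[need])) stop("marker trajectory contains missing frames")
  check_uniform_time(df$time)
  class(df) <- unique(c("marker_trajectory", class(df)))
  df
}

#' Footswitch trace container
#'
#' @param df Data frame with columns \code{time} (s) and \code{pressed}
#'   (1 = heel loaded, 0 = unloaded).
#' @export
footswitch_trace <- function(df) {
  miss <- setdiff(c("time", "pressed"), names(df))
  if (length(miss))
    stop("footswitch trace missing column(s): ", paste(miss, collapse = ", "))
  if (!all(df$pressed %in% c(0, 1))) stop("pressed must be 0/1")
  check_uniform_time(df$time)
  class(df) <- unique(c("footswitch_trace", class(df)))
  df
}

#' Zero-phase low-pass Butterworth filter
#'
#' Applies an order-\code{order} Butterworth low-pass filter
#' forward-backward (zero phase), the standard treatment of kinematic
#' signals before computing cycle metrics offline. Length and timestamps
#' are preserved; the DC gain is one.
#'
#' @param x Numeric series, uniformly sampled.
#' @param sample_rate Sampling rate, Hz.
#' @param cutoff_hz Cutoff frequency, Hz (must be below Nyquist).
#' @param order Filter order (default 2).
#' @return Filtered series, same length as \code{x}.
#' @export
lowpass_filter <- function(x, sample_rate = 100, cutoff_hz = 15, order = 2) {
  if (cutoff_hz >= sample_rate / 2)
    stop("cutoff must be below the Nyquist frequency ", sample_rate / 2, " Hz")
  if (length(x) < 3 * order)
    stop("series too short for filter order ", order)
  bf <- signal::butter(order, cutoff_hz / (sample_rate / 2), type = "low")
  # odd-reflection padding suppresses the forward-backward edge transients
  n <- length(x)
  pad <- min(n - 1, 3 * ceiling(sample_rate / cutoff_hz))
  xp <- c(2 * x[1] - x[seq(pad + 1, 2)], x,
          2 * x[n] - x[seq(n - 1, n - pad)])
  y <- as.numeric(signal::filtfilt(bf$b, bf$a, xp))
  y[(pad + 1):(pad + n)]
}

#' Low-pass filter a joint-angle trace
#'
#' @param angles A \code{joint_angle_trace} (see [compute_joint_angles()]).
#' @inheritParams lowpass_filter
#' @export
filter_angles <- function(angles, cutoff_hz = 15, order = 2) {
  check_uniform_time(angles$time)
  fs <- 1 / stats::median(diff(angles$time))
  angles$ankle_angle <- lowpass_filter(angles$ankle_angle, fs, cutoff_hz, order)
  angles$knee_angle <- lowpass_filter(angles$knee_angle, fs, cutoff_hz, order)
  angles
}

# signed angle (deg) from vector p to q in the sagittal (z, y) plane,
# counterclockwise positive; p, q are n x 2 matrices with columns (z, y)
signed_angle <- function(p, q) {
  cross <- p[, 1] * q[, 2] - p[, 2] * q[, 1]
  dot <- p[, 1] * q[, 1] + p[, 2] * q[, 2]
  atan2(cross, dot) * 180 / pi
}

#' Sagittal-plane joint angles from marker positions
#'
#' Knee angle: angle between the thigh segment (thigh -> knee) and the
#' shank segment (knee -> ankle), zero at full extension, flexion positive.
#' Ankle angle: angle between the shank segment and the foot segment
#' (ankle -> toe), zero in the anatomical neutral posture (shank
#' perpendicular to foot), dorsiflexion positive, plantar flexion negative.
#' All angles are computed in the sagittal (y-z) plane.
#'
#' @param markers A [marker_trajectory()].
#' @param min_segment Minimum admissible marker separation, m.
#' @return Data frame (class \code{joint_angle_trace}) with columns
#'   \code{time}, \code{ankle_angle}, \code{knee_angle} (degrees).
#' @export
compute_joint_angles <- function(markers, min_segment = 1e-3) {
  markers <- marker_trajectory(as.data.frame(markers))
  seg <- function(from, to) {
    cbind(markers[[paste0(to, "_z")]] - markers[[paste0(from, "_z")]],
          markers[[paste0(to, "_y")]] - markers[[paste0(from, "_y")]])
  }
  u_t <- seg("thigh", "knee")
  u_s <- seg("knee", "ankle")
  u_f <- seg("ankle", "toe")
  lens <- cbind(sqrt(rowSums(u_t^2)), sqrt(rowSums(u_s^2)), sqrt(rowSums(u_f^2)))
  if (any(lens < min_segment))
    stop("coincident markers (segment < ", min_segment, " m) at frame ",
         which(apply(lens < min_segment, 1, any))[1])
  knee <- -signed_angle(u_t, u_s)
  ankle <- signed_angle(u_s, u_f) - 90
  out <- data.frame(time = markers$time, ankle_angle = ankle, knee_angle = knee)
  class(out) <- c("joint_angle_trace", class(out))
  out
}

debounced_transitions <- function(fs, debounce) {
  p <- as.integer(fs$pressed)
  r <- rle(p)
  idx <- cumsum(r$lengths)
  n <- length(r$lengths)
  if (n < 2) return(data.frame(time = numeric(0), to = integer(0)))
  tt <- fs$time[idx[-n] + 1]     # raw transition times
  to <- r$values[-1]             # state after each transition
  from <- r$values[-n]
  # group transitions separated by less than the debounce interval; a group
  # collapses to a single transition at its first edge (or to none, for a
  # blip returning to the original state)
  grp <- cumsum(c(TRUE, diff(tt) >= debounce))
  out_t <- numeric(0); out_to <- integer(0)
  for (g in unique(grp)) {
    sel <- which(grp == g)
    s_from <- from[sel[1]]
    s_to <- to[sel[length(sel)]]
    if (s_from != s_to) {
      out_t <- c(out_t, tt[sel[1]])
      out_to <- c(out_to, s_to)
    }
  }
  data.frame(time = out_t, to = out_to)
}

#' Detect gait events from footswitch and toe kinematics
#'
#' Heel-off is each (debounced) 1 -> 0 footswitch transition, heel-strike
#' each 0 -> 1 transition. A cycle spans consecutive heel-strikes;
#' incomplete boundary cycles are discarded. Toe-off, which a single heel
#' footswitch cannot sense, is detected kinematically: the first sample
#' after heel-off at which the toe marker's vertical coordinate rises more
#' than \code{toe_lift_threshold} above its stance-phase median.
#'
#' @param fs A [footswitch_trace()].
#' @param markers Optional [marker_trajectory()] time-aligned with
#'   \code{fs}; without it toe-off is \code{NA}.
#' @param debounce Transitions closer than this (s) are merged.
#' @param toe_lift_threshold Toe vertical rise marking toe-off, m.
#' @return Data frame (class \code{gait_event_table}) with columns
#'   \code{cycle}, \code{start_time} (heel-strike opening the cycle),
#'   \code{heel_off}, \code{toe_off}, \code{heel_strike} (closing). Within
#'   every cycle \code{heel_off < toe_off < heel_strike}.
#' @export
detect_gait_events <- function(fs, markers = NULL, debounce = 0.05,
                               toe_lift_threshold = 0.005) {
  fs <- footswitch_trace(as.data.frame(fs))
  tr <- debounced_transitions(fs, debounce)
  empty <- data.frame(cycle = integer(0), start_time = numeric(0),
                      heel_off = numeric(0), toe_off = numeric(0),
                      heel_strike = numeric(0))
  class(empty) <- c("gait_event_table", class(empty))
  if (nrow(tr) == 0) {
    warning("no footswitch transitions found; empty event table")
    return(empty)
  }
  hs <- tr$time[tr$to == 1]
  ho <- tr$time[tr$to == 0]
  if (length(hs) < 1 || length(ho) < 1) {
    warning("no complete gait cycle found; empty event table")
    return(empty)
  }
  # cycles start at a heel-strike; the footswitch may already be pressed at
  # the start of the trace, in which case the trace's first sample opens a
  # provisional cycle only if a heel-off precedes the first heel-strike
  starts <- if (ho[1] < min(hs) && fs$pressed[1] == 1) c(fs$time[1], hs) else hs
  out <- list()
  k <- 0L
  for (i in seq_len(length(starts) - 1)) {
    s <- starts[i]; e <- starts[i + 1]
    h <- ho[ho > s & ho < e]
    if (length(h) != 1) {
      message("cycle starting at ", s, " dropped: ", length(h),
              " heel-off events inside")
      next
    }
    to <- NA_real_
    if (!is.null(markers)) {
      st <- markers$time >= s & markers$time <= h
      sw <- markers$time > h & markers$time < e
      if (any(st) && any(sw)) {
        lift <- stats::median(markers$toe_y[st]) + toe_lift_threshold
        j <- which(markers$toe_y[sw] > lift)
        if (length(j)) to <- markers$time[sw][j[1]]
      }
      if (is.na(to) || !(to > h && to < e)) {
        message("cycle starting at ", s, " dropped: toe-off not detected ",
                "between heel-off and heel-strike")
        next
      }
    }
    k <- k + 1L
    out[[k]] <- data.frame(cycle = k, start_time = s, heel_off = h,
                           toe_off = to, heel_strike = e)
  }
  if (!length(out)) {
    warning("no complete gait cycle found; empty event table")
    return(empty)
  }
  res <- do.call(rbind, out)
  class(res) <- c("gait_event_table", class(res))
  res
}

#' Per-step walking speed from the toe marker
#'
#' On a treadmill the body is quasi-stationary and the planted foot tracks
#' the belt, so the raw step speed is the magnitude of the posterior
#' displacement of the toe z coordinate during stance (heel-strike to
#' toe-off) divided by the stance duration. The smoothed speed \code{n_s}
#' is the mean of the most recent (up to) five raw step speeds.
#'
#' @param toe_z Toe marker z coordinate series, m.
#' @param time Sample times for \code{toe_z}, s.
#' @param events A \code{gait_event_table} covering the series.
#' @param window Number of steps averaged for \code{n_s} (default 5).
#' @return Data frame (class \code{speed_series}) with columns \code{cycle},
#'   \code{raw_speed}, \code{n_s} (m/s).
#' @export
estimate_speed <- function(toe_z, time, events, window = 5) {
  out <- data.frame(cycle = integer(0), raw_speed = numeric(0),
                    n_s = numeric(0))
  raws <- numeric(0)
  for (i in seq_len(nrow(events))) {
    s <- events$start_time[i]; to <- events$toe_off[i]
    if (is.na(to) || to <= s) next
    i0 <- which.min(abs(time - s)); i1 <- which.min(abs(time - to))
    dur <- time[i1] - time[i0]
    if (dur <= 0) next
    raw <- abs(toe_z[i1] - toe_z[i0]) / dur
    raws <- c(raws, raw)
    recent <- raws[max(1, length(raws) - window + 1):length(raws)]
    out <- rbind(out, data.frame(cycle = events$cycle[i], raw_speed = raw,
                                 n_s = mean(recent)))
  }
  class(out) <- c("speed_series", class(out))
  out
}

#' Per-cycle kinematic outcome metrics
#'
#' For each gait cycle: the maximum ankle dorsiflexion angle over the swing
#' phase (toe-off to heel-strike), the ankle angle at the sample nearest
#' the toe-off event (negative = plantar flexion), and the maximum knee
#' flexion angle over swing.
#'
#' @param angles A \code{joint_angle_trace} (filter first for measured data;
#'   see [filter_angles()]).
#' @param events A \code{gait_event_table}.
#' @return Data frame (class \code{gait_metrics}) with columns \code{cycle},
#'   \code{theta_a}, \code{pf_at_toe_off}, \code{max_knee_flexion} (deg).
#' @export
compute_gait_metrics <- function(angles, events) {
  out <- list(); k <- 0L
  for (i in seq_len(nrow(events))) {
    to <- events$toe_off[i]; hs <- events$heel_strike[i]
    if (is.na(to)) {
      warning("cycle ", events$cycle[i], " dropped: no toe-off event")
      next
    }
    sw <- angles$time >= to & angles$time <= hs
    if (sum(sw) < 2) {
      warning("cycle ", events$cycle[i], " dropped: swing window has < 2 samples")
      next
    }
    k <- k + 1L
    out[[k]] <- data.frame(
      cycle = events$cycle[i],
      theta_a = max(angles$ankle_angle[sw]),
      pf_at_toe_off = angles$ankle_angle[which.min(abs(angles$time - to))],
      max_knee_flexion = max(angles$knee_angle[sw]))
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(cycle = integer(0), theta_a = numeric(0),
               pf_at_toe_off = numeric(0), max_knee_flexion = numeric(0))
  class(res) <- c("gait_metrics", class(res))
  res
}
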