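test_that("zero-phase Butterworth filtering preserves DC and passband, rejects stopband", {
  fs <- 100
  # constant series: DC gain is exactly 1
  expect_equal(lowpass_filter(rep(3, 200), fs), rep(3, 200))
  t <- seq(0, 5, by = 1 / fs)
  # 1 Hz sine well inside the 15 Hz passband: amplitude within 1% of 1
  y1 <- lowpass_filter(sin(2 * pi * 1 * t), fs)
  expect_lt(abs(max(abs(y1[150:350])) - 1), 0.01)
  # 30 Hz sine: the analog two-pass magnitude 1/(1+(30/15)^4) = 0.0588 is an
  # upper bound; the digital realisation attenuates at least as strongly
  y30 <- lowpass_filter(sin(2 * pi * 30 * t), fs)
  expect_lt(max(abs(y30[150:350])), 1 / (1 + (30 / 15)^4) * 1.01)
  expect_length(y30, length(t))
})

test_that("filter rejects invalid parameters", {
  expect_error(lowpass_filter(rnorm(100), 100, cutoff_hz = 50), "Nyquist")
  expect_error(lowpass_filter(rnorm(4), 100, order = 2), "too short")
  expect_error(filter_angles(data.frame(time = c(0, 0.01, 0.5),
                                        ankle_angle = 1:3, knee_angle = 1:3)),
               "non-uniform")
})

test_that("joint angles follow the neutral/extension conventions", {
  # vertical shank, horizontal anterior foot: neutral ankle, extended knee
  mk <- static_markers(thigh = c(0, 1.02), knee = c(0, 0.60),
                       shank = c(0, 0.385), ankle = c(0, 0.17),
                       toe = c(0.19, 0.17))
  ja <- compute_joint_angles(mk)
  expect_equal(ja$ankle_angle, rep(0, 5), tolerance = 1e-10)
  expect_equal(ja$knee_angle, rep(0, 5), tolerance = 1e-10)
  # dorsiflexion positive: lift the toe
  mk2 <- static_markers(thigh = c(0, 1.02), knee = c(0, 0.60),
                        shank = c(0, 0.385), ankle = c(0, 0.17),
                        toe = c(0.19 * cos(0.2), 0.17 + 0.19 * sin(0.2)))
  expect_gt(compute_joint_angles(mk2)$ankle_angle[1], 0)
})

test_that("joint angle computation errors on degenerate input", {
  mk <- static_markers(thigh = c(0, 1.02), knee = c(0, 0.60),
                       shank = c(0, 0.385), ankle = c(0, 0.17),
                       toe = c(0.0002, 0.17))
  expect_error(compute_joint_angles(mk), "coincident")
  bad <- as.data.frame(mk)[, -ncol(mk)]
  expect_error(compute_joint_angles(bad), "missing column")
})

test_that("angles round-trip through the forward kinematics within 0.1 degree", {
  p <- plant_params()
  n <- 120
  ang <- data.frame(time = (0:(n - 1)) / 100,
                    ankle_angle = rep(10, n), knee_angle = rep(30, n))
  class(ang) <- c("joint_angle_trace", class(ang))
  rec <- compute_joint_angles(forward_kinematics(ang, p, v = 1))
  expect_lt(max(abs(rec$ankle_angle - 10)), 0.1)
  expect_lt(max(abs(rec$knee_angle - 30)), 0.1)
  # and on a full plant-generated cycle
  sim <- simulate_cycle(1, 0, NULL, p, noise = FALSE)
  rec2 <- compute_joint_angles(forward_kinematics(sim$angles, p, 1, sim$phase))
  expect_lt(max(abs(rec2$ankle_angle - sim$angles$ankle_angle)), 0.1)
  expect_lt(max(abs(rec2$knee_angle - sim$angles$knee_angle)), 0.1)
})

test_that("footswitch transitions give heel-off and heel-strike events", {
  t <- seq(0, 2.0, by = 0.01)
  pressed <- as.integer(t < 0.6 | t >= 1.0)
  ev <- detect_gait_events(footswitch_trace(data.frame(time = t, pressed = pressed)))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$heel_off, 0.6)
  expect_equal(ev$start_time, 0)
  expect_equal(ev$heel_strike, 1.0)
  # constant pressed: no transitions
  expect_warning(
    ev0 <- detect_gait_events(
      footswitch_trace(data.frame(time = t, pressed = rep(1L, length(t))))),
    "no footswitch transitions")
  expect_equal(nrow(ev0), 0)
})

test_that("switch bounce within the debounce interval is merged", {
  t <- seq(0, 2.0, by = 0.01)
  pressed <- as.integer(t < 0.6 | t >= 1.0)
  pressed[t >= 0.62 & t < 0.65] <- 1L  # 30 ms bounce after heel-off
  ev <- detect_gait_events(footswitch_trace(data.frame(time = t, pressed = pressed)))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$heel_off, 0.6)
})

test_that("detected events match plant ground truth within one sample", {
  tr <- ns_recording(n_cycles = 8, seed = 7, noise = FALSE)
  rec <- tr$recording
  ev <- detect_gait_events(rec$footswitch, rec$markers)
  truth <- rec$events
  expect_gte(nrow(ev), 6)
  for (i in seq_len(nrow(ev))) {
    k <- which.min(abs(truth$start_time - ev$start_time[i]))
    expect_lt(abs(ev$heel_off[i] - truth$heel_off[k]), 0.0101)
    expect_lt(abs(ev$heel_strike[i] - truth$heel_strike[k]), 0.0101)
    expect_lt(abs(ev$toe_off[i] - truth$toe_off[k]), 0.0101)
  }
  # ordering invariant
  expect_true(all(ev$heel_off < ev$toe_off & ev$toe_off < ev$heel_strike))
  expect_true(all(diff(ev$start_time) > 0))
})

test_that("step speed is displacement over stance duration, smoothed over five steps", {
  # toe moving posteriorly at 1.2 m/s during a 0.6 s stance
  t <- seq(0, 1.0, by = 0.01)
  toe_z <- 0.15 - 1.2 * t
  ev <- data.frame(cycle = 1L, start_time = 0, heel_off = 0.4, toe_off = 0.6,
                   heel_strike = 1.0)
  sp <- estimate_speed(toe_z, t, ev)
  expect_equal(sp$raw_speed, 1.2, tolerance = 1e-9)
  expect_equal(sp$n_s, 1.2, tolerance = 1e-9)
  # n_s is the arithmetic mean of the recent raw speeds
  ev5 <- data.frame(cycle = 1:5, start_time = 0:4, heel_off = 0:4 + 0.4,
                    toe_off = 0:4 + 0.5, heel_strike = 1:5)
  speeds <- c(0.8, 0.9, 1.0, 1.1, 1.2)
  tt <- seq(0, 5, by = 0.01)
  zz <- numeric(length(tt))
  for (i in 1:5) {
    seg <- tt >= (i - 1) & tt <= (i - 1) + 0.5
    zz[seg] <- -speeds[i] * (tt[seg] - (i - 1))
  }
  sp5 <- estimate_speed(zz, tt, ev5)
  expect_equal(sp5$raw_speed, speeds, tolerance = 1e-9)
  expect_equal(sp5$n_s[5], 1.0, tolerance = 1e-9)
  expect_equal(sp5$n_s[3], mean(speeds[1:3]), tolerance = 1e-9)
})

test_that("commanded belt speed is recovered within 5% after five steps", {
  for (v_label in c("slow", "free", "fast")) {
    tr <- ns_recording(n_cycles = 8, seed = 3, v_label = v_label)
    rec <- tr$recording
    ev <- detect_gait_events(rec$footswitch, rec$markers)
    sp <- estimate_speed(rec$markers$toe_z, rec$markers$time, ev)
    v <- tr$cycles$commanded_speed[1]
    expect_lt(abs(tail(sp$n_s, 1) - v) / v, 0.05)
  }
})

test_that("cycle metrics pick swing extrema and the toe-off sample", {
  t <- seq(0, 1.5, by = 0.01)
  ankle <- rep(-1, length(t))
  ankle[t >= 0.62 & t < 1.0] <- 4.2 * sin(pi * (t[t >= 0.62 & t < 1.0] - 0.62) / 0.38)
  ankle[abs(t - 0.62) < 1e-9] <- -4.6
  knee <- rep(5, length(t))
  knee[t >= 0.62 & t < 1.0] <- 33.3 * sin(pi * (t[t >= 0.62 & t < 1.0] - 0.62) / 0.38)
  ang <- data.frame(time = t, ankle_angle = ankle, knee_angle = knee)
  ev <- data.frame(cycle = 1L, start_time = 0, heel_off = 0.45, toe_off = 0.62,
                   heel_strike = 1.0)
  m <- compute_gait_metrics(ang, ev)
  expect_equal(m$theta_a, max(ankle[t >= 0.62 & t <= 1.0]))
  expect_equal(m$pf_at_toe_off, -4.6)
  expect_equal(m$max_knee_flexion, max(knee[t >= 0.62 & t <= 1.0]))
  # a swing window with fewer than two samples drops the cycle
  ev2 <- ev; ev2$toe_off <- 0.995
  expect_warning(m2 <- compute_gait_metrics(ang, ev2), "swing window")
  expect_equal(nrow(m2), 0)
})

test_that("metrics are invariant to a global time shift", {
  tr <- ns_recording(n_cycles = 5, seed = 11, noise = FALSE)
  rec <- tr$recording
  shift <- 37.5
  mk2 <- rec$markers; mk2$time <- mk2$time + shift
  fs2 <- rec$footswitch; fs2$time <- fs2$time + shift
  ev1 <- detect_gait_events(rec$footswitch, rec$markers)
  ev2 <- detect_gait_events(fs2, mk2)
  m1 <- compute_gait_metrics(compute_joint_angles(rec$markers), ev1)
  m2 <- compute_gait_metrics(compute_joint_angles(mk2), ev2)
  expect_equal(m2$theta_a, m1$theta_a, tolerance = 1e-9)
  expect_equal(m2$pf_at_toe_off, m1$pf_at_toe_off, tolerance = 1e-9)
  expect_equal(ev2$heel_off - shift, ev1$heel_off, tolerance = 1e-9)
})
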