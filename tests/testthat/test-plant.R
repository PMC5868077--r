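test_that("recruitment curve: threshold, monotonicity, saturation", {
  p <- plant_params()
  expect_equal(recruitment(0, p), 0)
  expect_equal(recruitment(p$recruitment_threshold, p), 0)
  # exhaustive 1 mA sweep: non-decreasing
  r <- recruitment(0:120, p)
  expect_true(all(diff(r) >= 0))
  expect_true(all(r >= 0 & r <= 1))
  # derived saturation amplitudes hit their levels
  expect_equal(recruitment(recruitment_saturation(p, 0.95), p), 0.95,
               tolerance = 1e-9)
  expect_gt(recruitment(recruitment_saturation(p, 0.99) + 100, p), 0.99)
})

test_that("activation follows first-order dynamics exactly", {
  p <- plant_params()
  t <- seq(0, 1, by = 0.01)
  # no stimulation: identically zero
  a0 <- activation_dynamics(0, hos_window(0, 1), t, p)
  expect_true(all(a0$activation == 0))
  # constant window from t = 0: matches the closed-form step response
  amp <- 60
  act <- activation_dynamics(amp, hos_window(0, 2), t, p)
  closed <- recruitment(amp, p) * (1 - exp(-t / p$tau_act))
  expect_equal(act$activation, closed, tolerance = 1e-3)
  # after 5 time constants: within 1% of the recruitment level
  i5 <- which(t >= 5 * p$tau_act)[1]
  expect_lt(abs(act$activation[i5] - recruitment(amp, p)) /
              recruitment(amp, p), 0.01)
  # decay phase uses tau_deact
  act2 <- activation_dynamics(amp, hos_window(0, 0.5), t, p)
  off <- t > 0.5
  a_off <- act2$activation[off][1]
  expect_lt(act2$activation[length(t)], a_off)
  expect_true(all(diff(act2$activation[off]) <= 0))
})

test_that("unstimulated cycle reproduces the configured dropfoot baseline", {
  p <- plant_params()
  sim <- simulate_cycle(1, 0, NULL, p, noise = FALSE)
  swing <- sim$phase >= p$stance_fraction
  expect_equal(max(sim$angles$ankle_angle[swing]), p$swing_dorsiflexion_peak,
               tolerance = 1e-9)
  i_to <- which.min(abs(sim$phase - p$stance_fraction))
  expect_equal(sim$angles$ankle_angle[i_to], p$pf_at_toe_off, tolerance = 0.05)
  # the knee peak control point need not fall on a sample
  expect_equal(max(sim$angles$knee_angle[swing]), p$knee_peak,
               tolerance = 0.05)
})

test_that("saturated stimulation adds the full dorsiflexion gain", {
  # a subject whose muscle saturates within the stimulator range
  p <- suppressWarnings(plant_params(recruitment_scale = 25,
                                     recruitment_shape = 1,
                                     tau_act = 0.04))
  T <- p$cycle_intercept + p$cycle_slope * 1
  w <- hos_window(p$heel_off_fraction * T, T)
  sim <- simulate_cycle(1, 120, w, p, noise = FALSE)
  swing <- sim$phase >= p$stance_fraction
  peak <- max(sim$angles$ankle_angle[swing])
  target <- p$swing_dorsiflexion_peak + p$max_added_dorsiflexion
  expect_lt(abs(peak - target) / target, 0.01)
})

test_that("plant response is monotone in amplitude at fixed timing", {
  p <- plant_params()
  T <- p$cycle_intercept + p$cycle_slope * 1
  w <- build_window(p$heel_off_fraction * T, T, 1.0)
  peaks <- vapply(seq(0, 120, by = 1), function(a) {
    sim <- simulate_cycle(1, a, w, p, noise = FALSE)
    max(sim$angles$ankle_angle[sim$phase >= p$stance_fraction])
  }, 0)
  expect_true(all(diff(peaks) >= -1e-9))
})

test_that("simulation is deterministic under a fixed seed", {
  p <- plant_params()
  set.seed(123); s1 <- simulate_cycle(1, 30, NULL, p)
  set.seed(123); s2 <- simulate_cycle(1, 30, NULL, p)
  expect_identical(s1$angles, s2$angles)
  set.seed(124); s3 <- simulate_cycle(1, 30, NULL, p)
  expect_false(identical(s1$angles$ankle_angle, s3$angles$ankle_angle))
  expect_error(simulate_cycle(5, 0, NULL, p), "outside")
})

test_that("forward kinematics: neutral posture and belt-speed consistency", {
  p <- plant_params(thigh_swing_deg = 0)
  n <- 50
  ang <- data.frame(time = (0:(n - 1)) / 100,
                    ankle_angle = numeric(n), knee_angle = numeric(n))
  mk <- forward_kinematics(ang, p, v = 1)
  # shank vertical: knee directly above ankle
  expect_equal(mk$knee_z, mk$ankle_z, tolerance = 1e-12)
  expect_equal(mk$knee_y - mk$ankle_y, rep(p$shank_length, n),
               tolerance = 1e-12)
  # foot horizontal, toe anterior
  expect_equal(mk$toe_y, mk$ankle_y, tolerance = 1e-12)
  expect_equal(mk$toe_z - mk$ankle_z, rep(p$foot_length, n),
               tolerance = 1e-12)
})

test_that("stance-phase toe translation matches the belt speed within 1%", {
  p <- plant_params()
  for (v in c(0.725, 1.0, 1.275)) {
    sim <- simulate_cycle(v, 0, NULL, p, noise = FALSE)
    mk <- forward_kinematics(sim$angles, p, v, sim$phase)
    st <- sim$phase <= p$stance_fraction
    dz <- mk$toe_z[st][1] - mk$toe_z[st][sum(st)]
    dt <- mk$time[st][sum(st)] - mk$time[st][1]
    expect_lt(abs(dz / dt - v) / v, 0.01)
  }
})

test_that("footswitch rendering matches the event schedule", {
  t <- seq(0, 0.99, by = 0.01)
  ev <- data.frame(cycle = 1L, start_time = 0, heel_off = 0.62,
                   toe_off = 0.7, heel_strike = 1.0)
  fs <- generate_footswitch(ev, t)
  expect_equal(sum(fs$pressed), 62)
  expect_equal(fs$time[which(fs$pressed == 0)[1]], 0.62)
  fs0 <- generate_footswitch(ev[0, ], t)
  expect_true(all(fs0$pressed == 0))
})

test_that("noise-on unstimulated dorsiflexion stays calibrated in the mean", {
  tr <- run_trial(trial_config("NS", "free", seed = 5, n_cycles = 50))
  expect_lt(abs(mean(tr$cycles$theta_a, na.rm = TRUE) - 0.7), 0.2)
})

test_that("an unreachable setpoint is flagged at configuration load", {
  expect_warning(plant_params(max_added_dorsiflexion = 3), "unreachable")
  expect_silent(plant_params())
})
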