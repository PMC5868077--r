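# shared fixtures and independent oracles, built in code at test time

# brute-force centroid of an aggregated output membership function by
# trapezoidal integration on a dense grid; independent of the package's
# defuzzification path
oracle_centroid <- function(aggregate, n = 10001) {
  u <- aggregate$output$universe
  x <- seq(u[1], u[2], length.out = n)
  mu <- aggregate_degree(aggregate, x)
  w <- rep(1, n); w[c(1, n)] <- 0.5
  sum(w * x * mu) / sum(w * mu)
}

# a quiet NS recording with full traces, for event/speed tests
ns_recording <- function(n_cycles = 8, seed = 7, v_label = "free",
                         noise = TRUE) {
  p <- plant_params()
  if (!noise) p$noise_sd <- p$sensor_noise_sd <- 0
  run_trial(trial_config("NS", v_label, seed = seed, n_cycles = n_cycles),
            plant = p, keep_recording = TRUE)
}

# markers for a single static posture (one frame repeated), given segment
# endpoints in the sagittal plane
static_markers <- function(thigh, knee, shank, ankle, toe, n = 5) {
  df <- data.frame(time = (0:(n - 1)) / 100)
  pts <- list(thigh = thigh, knee = knee, shank = shank, ankle = ankle,
              toe = toe)
  for (m in names(pts)) {
    df[[paste0(m, "_x")]] <- 0.1
    df[[paste0(m, "_y")]] <- pts[[m]][2]
    df[[paste0(m, "_z")]] <- pts[[m]][1]
  }
  marker_trajectory(df)
}
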