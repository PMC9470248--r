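# Small shared fixtures; built in code, scaled for test runtime.

tiny_config <- function(rate = 100, trials = 25, blocks = 2, ...) {
  session_config(sampling_rate = rate, n_blocks = blocks,
                 trials_per_block = trials, ...)
}

# truth with every stochastic nuisance switched off
clean_truth <- function(amp = c(standard = -0.3, oddball = 1.4, deviant = 0.5),
                        ...) {
  ground_truth(
    amp = amp, noise_sd = 0, tonic_sd = 0,
    amp_sd = c(standard = 0, oddball = 0, deviant = 0),
    blink_rate_per_min = 0, gaze_excursion_rate_per_min = 0,
    drift_slope_mm2_min = 0, calib_noise_au = 0, ...
  )
}

# regular sample tibble on a clean grid
grid_samples <- function(n, rate = 500, pupil = rep(1000, n),
                         gaze_x = rep(0, n), gaze_y = rep(0, n)) {
  dt <- 1000 / rate
  tibble::tibble(
    time_ms = (seq_len(n) - 1) * dt,
    gaze_x_deg = gaze_x,
    gaze_y_deg = gaze_y,
    pupil_au = pupil
  )
}

identity_curve <- function() {
  fit_calibration(tibble::tibble(measured_au = c(0, 1, 2),
                                 true_area_mm2 = c(0, 1, 2) + 1e-9))
}
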