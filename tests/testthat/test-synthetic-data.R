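test_that("tone plans realise exact per-type counts, shuffled, with jittered onsets", {
  for (case in list(c(250, 20, 20, 210), c(125, 10, 10, 105))) {
    cfg <- tiny_config(trials = case[1])
    ev <- plan_tones(cfg, 1, seed = 11)
    counts <- table(ev$trial_type)
    expect_equal(unname(counts["oddball"]), case[2])
    expect_equal(unname(counts["deviant"]), case[3])
    expect_equal(unname(counts["standard"]), case[4])
    itis <- diff(ev$onset_ms)
    expect_true(all(itis >= cfg$iti_range_ms[1] - 1 &
                      itis <= cfg$iti_range_ms[2] + 1))
  }
})

test_that("tone frequencies follow the counterbalance flag", {
  ev_hi <- plan_tones(tiny_config(counterbalance = "oddball_high"), 1, seed = 2)
  expect_equal(unique(ev_hi$tone_hz[ev_hi$trial_type == "standard"]), 1400)
  expect_equal(unique(ev_hi$tone_hz[ev_hi$trial_type == "oddball"]), 1600)
  expect_equal(unique(ev_hi$tone_hz[ev_hi$trial_type == "deviant"]), 1200)
  ev_lo <- plan_tones(tiny_config(counterbalance = "oddball_low"), 1, seed = 2)
  expect_equal(unique(ev_lo$tone_hz[ev_lo$trial_type == "oddball"]), 1200)
  expect_equal(unique(ev_lo$tone_hz[ev_lo$trial_type == "deviant"]), 1600)
})

test_that("tone planning is deterministic under a fixed seed and rejects fractional counts", {
  cfg <- tiny_config(trials = 50)
  expect_identical(plan_tones(cfg, 1, seed = 7), plan_tones(cfg, 1, seed = 7))
  expect_error(session_config(trials_per_block = 100, p_oddball = 0.085),
               "integer")
})

test_that("the pupil kernel peaks at 1, vanishes at onset, and is unimodal", {
  expect_equal(pupil_kernel(930), 1.0)
  expect_equal(pupil_kernel(0), 0.0)
  expect_equal(pupil_kernel(-50), 0.0)
  t <- seq(1, 5000, by = 1)
  k <- pupil_kernel(t)
  d <- diff(k)
  peak <- which.max(k)
  expect_true(all(d[seq_len(peak - 1)] > 0))
  expect_true(all(d[peak:length(d)] < 0))
  expect_lt(abs(t[peak] - 930), 2)
})

test_that("trace synthesis is the analytic kernel superposition when noise is off", {
  cfg <- tiny_config(rate = 500, trials = 25)
  tr <- clean_truth()
  ev <- plan_tones(cfg, 1, seed = 3)
  peaks <- c(standard = -0.5, oddball = 2, deviant = 1)

  # all amplitudes zero: constant at the tonic level
  flat <- simulate_trace(ev, tr, cfg, peak_amps = c(standard = 0, oddball = 0,
                                                    deviant = 0),
                         noise = FALSE, as_au = FALSE)
  expect_equal(flat$pupil_mm2, rep(tr$tonic_level[["none"]], nrow(flat)))

  # single event: trace minus tonic equals amp * kernel exactly
  one <- ev[3, ]
  tt <- simulate_trace(one, tr, cfg, peak_amps = peaks, noise = FALSE,
                       as_au = FALSE)
  expected <- peaks[[one$trial_type]] *
    pupil_kernel(tt$time_ms - one$onset_ms, tr$kernel_n, tr$kernel_tmax_ms)
  expect_equal(tt$pupil_mm2 - tr$tonic_level[["none"]], expected,
               tolerance = 1e-12)

  # full sequence: superposition of per-event kernels; doubling peaks doubles it
  seq1 <- simulate_trace(ev, tr, cfg, peak_amps = peaks, noise = FALSE,
                         as_au = FALSE)
  analytic <- rep(0, nrow(seq1))
  for (i in seq_len(nrow(ev))) {
    analytic <- analytic + peaks[[ev$trial_type[i]]] *
      pupil_kernel(seq1$time_ms - ev$onset_ms[i], tr$kernel_n,
                   tr$kernel_tmax_ms)
  }
  dev1 <- seq1$pupil_mm2 - tr$tonic_level[["none"]]
  expect_equal(dev1, analytic, tolerance = 1e-6)
  seq2 <- simulate_trace(ev, tr, cfg, peak_amps = peaks * 2, noise = FALSE,
                         as_au = FALSE)
  expect_equal(seq2$pupil_mm2 - tr$tonic_level[["none"]], 2 * dev1,
               tolerance = 1e-9)
})

test_that("blink injection produces the requested missing runs and nothing else", {
  s <- grid_samples(2000, rate = 500)
  tr <- clean_truth()

  none <- inject_blinks(s, ground_truth(blink_rate_per_min = 0))
  expect_identical(none$pupil_au, s$pupil_au)

  one <- inject_blinks(s, tr, blinks = tibble::tibble(start_ms = 1000,
                                                      duration_ms = 150))
  runs <- detect_missing_runs(one)
  expect_equal(nrow(runs), 1)
  expect_equal(runs$end_ms - runs$start_ms, 150)
  # instability confined to the ramp just outside the run
  touched <- which(one$pupil_au != s$pupil_au & !is.na(one$pupil_au))
  expect_true(all(abs(s$time_ms[touched] - 1000) <= tr$blink_ramp_ms |
                    abs(s$time_ms[touched] - 1150) <= tr$blink_ramp_ms))
})

test_that("gaze stays inside 2 degrees without excursions; excursions are masked by the gaze rule", {
  s <- grid_samples(30000, rate = 500)
  set.seed(5)
  quiet <- simulate_gaze(s, ground_truth(gaze_excursion_rate_per_min = 0))
  expect_lt(max(sqrt(quiet$gaze_x_deg^2 + quiet$gaze_y_deg^2)), 2)

  set.seed(5)
  again <- simulate_gaze(s, ground_truth(gaze_excursion_rate_per_min = 0))
  expect_identical(quiet$gaze_x_deg, again$gaze_x_deg)

  set.seed(9)
  wander <- simulate_gaze(s, ground_truth(gaze_excursion_rate_per_min = 30))
  exc <- attr(wander, "excursions")
  expect_gt(nrow(exc), 0)
  spans <- mask_gaze_deviation(wander, 2.0)
  inside_mask <- function(t) any(t >= spans$start_ms & t < spans$end_ms)
  mids <- (pmax(exc$start_ms, 0) + pmin(exc$end_ms, max(s$time_ms))) / 2
  expect_true(all(vapply(mids, inside_mask, logical(1))))
})

test_that("behaviour simulation respects error rates and reward-dependent RTs", {
  cfg <- tiny_config(trials = 500, blocks = 1)
  ev <- plan_tones(cfg, 1, seed = 21)

  perfect <- ground_truth(error_rates = c(oddball = 0, standard = 0, deviant = 0))
  set.seed(1)
  b <- simulate_behavior(ev, perfect, cfg, 1)
  expect_true(all(!is.na(b$response_time_ms[b$trial_type == "oddball"])))
  expect_true(all(is.na(b$response_time_ms[b$trial_type != "oddball"])))
  expect_true(all(classify_outcome(b) == "correct"))

  all_miss <- ground_truth(error_rates = c(oddball = 1, standard = 0, deviant = 0))
  set.seed(1)
  b2 <- simulate_behavior(ev, all_miss, cfg, 1)
  expect_equal(mean(classify_outcome(b2) == "error"), cfg$p_oddball)

  # faster responses under high reward (log-normal medians ordered)
  rt_truth <- ground_truth()
  cfg_hi <- session_config(n_blocks = 1, trials_per_block = 500,
                           reward_schedule = "high")
  cfg_lo <- session_config(n_blocks = 1, trials_per_block = 500,
                           reward_schedule = "low")
  set.seed(2)
  rt_hi <- simulate_behavior(plan_tones(cfg_hi, 1, seed = 4), rt_truth, cfg_hi, 1)
  set.seed(2)
  rt_lo <- simulate_behavior(plan_tones(cfg_lo, 1, seed = 4), rt_truth, cfg_lo, 1)
  expect_lt(median(rt_hi$response_time_ms[rt_hi$trial_type == "oddball"],
                   na.rm = TRUE),
            median(rt_lo$response_time_ms[rt_lo$trial_type == "oddball"],
                   na.rm = TRUE))

  # counting blocks collect no responses
  cfg_cnt <- session_config(n_blocks = 1, trials_per_block = 25,
                            block_modes = "counting")
  bc <- simulate_behavior(plan_tones(cfg_cnt, 1, seed = 5), rt_truth, cfg_cnt, 1)
  expect_true(all(is.na(bc$response_time_ms)))
})

test_that("overlap leakage coefficients match a brute-force unit-peak simulation", {
  # with every kernel peak = 1, the mean mid-sequence change score must equal
  # g + kappa and the mean baseline leakage must equal kappa_base
  cfg <- session_config(sampling_rate = 100, n_blocks = 1,
                        trials_per_block = 500, seed = 1)
  tr <- clean_truth()
  ev <- plan_tones(cfg, 1, seed = 2)
  trc <- simulate_trace(ev, tr, cfg,
                        peak_amps = c(standard = 1, oddball = 1, deviant = 1),
                        noise = FALSE, as_au = FALSE)
  sc <- score_trial(extract_epochs(trc, ev, 100)$epochs, 100)
  mid <- 6:(nrow(sc) - 5)  # exclude context-free sequence edges
  g <- oddpupil:::kernel_window_gain(tr$kernel_n, tr$kernel_tmax_ms, 100)
  ov <- oddpupil:::overlap_components(tr$kernel_n, tr$kernel_tmax_ms,
                                      cfg$iti_range_ms)
  expect_lt(abs(mean(sc$change[mid]) - (g + ov$kappa)), 0.015)
  expect_lt(abs(mean(sc$baseline_mean[mid]) - tr$tonic_level[["none"]] -
                  ov$kappa_base), 0.02)
  expect_lt(ov$kappa, 0)  # baseline window rides the previous response
})

test_that("sessions are deterministic given (config, truth, seed), on disk too", {
  cfg <- tiny_config(rate = 100, trials = 25)
  tr <- ground_truth()
  s1 <- simulate_session(cfg, tr, seed = 99)
  s2 <- simulate_session(cfg, tr, seed = 99)
  expect_identical(s1$samples, s2$samples)
  expect_identical(s1$events, s2$events)

  d1 <- file.path(tempdir(), "det1")
  d2 <- file.path(tempdir(), "det2")
  write_session(s1, d1)
  write_session(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)

  # count conservation: every block holds the exact planned mix
  counts <- table(s1$events$block_id, s1$events$trial_type)
  expect_true(all(counts[, "oddball"] == 2))
  expect_true(all(counts[, "deviant"] == 2))
  expect_true(all(counts[, "standard"] == 21))
})
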