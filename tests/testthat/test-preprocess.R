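test_that("missing runs are detected as maximal half-open spans", {
  s <- grid_samples(2000, rate = 500)
  s$pupil_au[s$time_ms >= 1000 & s$time_ms < 1150] <- NA
  spans <- detect_missing_runs(s)
  expect_equal(nrow(spans), 1)
  expect_equal(spans$start_ms, 1000)
  expect_equal(spans$end_ms, 1150)
  expect_equal(spans$reason, "blink")

  expect_equal(nrow(detect_missing_runs(grid_samples(100))), 0)

  s2 <- grid_samples(100, rate = 500)
  s2$pupil_au[c(10, 11, 13)] <- NA  # two runs separated by one valid sample
  expect_equal(nrow(detect_missing_runs(s2)), 2)
})

test_that("margin extension widens, clips and merges spans", {
  span <- function(a, b) tibble::tibble(start_ms = a, end_ms = b,
                                        reason = "blink")
  one <- extend_margins(span(1000, 1100), 200, block_range = c(0, 4000))
  expect_equal(c(one$start_ms, one$end_ms), c(800, 1300))

  two <- extend_margins(span(c(1000, 1350), c(1100, 1450)), 200,
                        block_range = c(0, 4000))
  expect_equal(nrow(two), 1)
  expect_equal(c(two$start_ms, two$end_ms), c(800, 1650))

  edge <- extend_margins(span(0, 100), 200, block_range = c(0, 4000))
  expect_equal(c(edge$start_ms, edge$end_ms), c(0, 300))
})

test_that("margin extension matches the boolean-timeline interval-union oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(3:12, 1)
    starts <- sort(sample(0:4500, n))
    spans <- tibble::tibble(
      start_ms = starts,
      end_ms = starts + sample(20:400, n, replace = TRUE),
      reason = "blink"
    )
    spans$end_ms <- pmin(spans$end_ms, 5000)
    got <- extend_margins(spans, 200, block_range = c(0, 5000))
    want <- oracle_extend_margins(spans, 200, c(0, 5000))
    expect_equal(got$start_ms, want$start_ms)
    expect_equal(got$end_ms, want$end_ms)
    # idempotence: the disjoint result is a fixed point of merging
    again <- merge_spans(got)
    expect_equal(again$start_ms, got$start_ms)
    expect_equal(again$end_ms, got$end_ms)
  }
})

test_that("gaze masking uses Euclidean distance with >= at the 2-degree boundary", {
  s <- grid_samples(4, rate = 500,
                    gaze_x = c(0, 3, 2.0, 1.2), gaze_y = c(0, 0, 0, 1.2))
  spans <- mask_gaze_deviation(s, 2.0)
  masked <- samples_masked <- rep(FALSE, 4)
  for (i in seq_len(nrow(spans))) {
    masked <- masked | (s$time_ms >= spans$start_ms[i] &
                          s$time_ms < spans$end_ms[i])
  }
  expect_equal(masked, c(FALSE, TRUE, TRUE, FALSE))
})

test_that("interpolation is the two-point line, holds edges, and touches only masked samples", {
  s <- grid_samples(4, rate = 500, pupil = c(4, NA, NA, 10))
  out <- interpolate_missing(s, detect_missing_runs(s))
  expect_equal(out$pupil_au, c(4, 6, 8, 10))
  expect_equal(out$interpolated, c(FALSE, TRUE, TRUE, FALSE))

  # constant stays constant through any gap
  s2 <- grid_samples(50, rate = 500, pupil = rep(7, 50))
  s2$pupil_au[10:20] <- NA
  expect_equal(interpolate_missing(s2, detect_missing_runs(s2))$pupil_au,
               rep(7, 50))

  # leading/trailing gaps hold the nearest valid value
  s3 <- grid_samples(6, rate = 500, pupil = c(NA, NA, 5, 6, NA, NA))
  expect_equal(interpolate_missing(s3, detect_missing_runs(s3))$pupil_au,
               c(5, 5, 5, 6, 6, 6))

  # random gaps on a quadratic: matches the brute-force oracle exactly
  for (seed in 1:5) {
    set.seed(seed)
    n <- 200
    s4 <- grid_samples(n, rate = 500)
    s4$pupil_au <- 1000 + 0.5 * s4$time_ms - 0.001 * s4$time_ms^2
    clean <- s4$pupil_au
    s4$pupil_au[sample(2:(n - 1), 40)] <- NA
    got <- interpolate_missing(s4, detect_missing_runs(s4))
    want <- oracle_interpolate(s4$time_ms, s4$pupil_au)
    expect_equal(got$pupil_au, want, tolerance = 1e-12)
    # untouched where valid
    expect_equal(got$pupil_au[!is.na(s4$pupil_au)],
                 clean[!is.na(s4$pupil_au)])
  }

  expect_error(
    interpolate_missing(grid_samples(5, pupil = rep(NA_real_, 5)),
                        tibble::tibble(start_ms = numeric(0),
                                       end_ms = numeric(0),
                                       reason = character(0))),
    "entire block"
  )
})

test_that("detrending removes the slope, preserves the mean, and is idempotent", {
  n <- 5000
  s <- grid_samples(n, rate = 500)
  s$pupil_au <- 900 + 0.02 * s$time_ms
  out <- detrend_block(s)
  expect_equal(out$pupil_au, rep(mean(s$pupil_au), n), tolerance = 1e-9)

  set.seed(3)
  s2 <- grid_samples(n, rate = 500, pupil = rnorm(n, 1000, 30))
  once <- detrend_block(s2)
  expect_equal(mean(once$pupil_au), mean(s2$pupil_au), tolerance = 1e-10)
  # refit slope of the output is numerically zero
  refit <- coef(lm(pupil_au ~ time_ms, data = once))[2]
  expect_lt(abs(refit), 1e-9)
  twice <- detrend_block(once)
  expect_equal(twice$pupil_au, once$pupil_au, tolerance = 1e-9)
})

test_that("calibration fits recover affine maps and report the OLS residual", {
  au <- c(1000, 2000, 3000, 4000, 5500)
  exact <- tibble::tibble(measured_au = au,
                          true_area_mm2 = 0.002 * au + 0.5)
  cv <- fit_calibration(exact)
  expect_equal(cv$slope, 0.002, tolerance = 1e-12)
  expect_equal(cv$intercept, 0.5, tolerance = 1e-10)
  expect_equal(cv$residual_rmse, 0, tolerance = 1e-10)

  ident <- tibble::tibble(measured_au = c(1, 2, 5), true_area_mm2 = c(1, 2, 5))
  ci <- fit_calibration(ident)
  expect_equal(ci$slope, 1, tolerance = 1e-12)
  expect_equal(ci$intercept, 0, tolerance = 1e-12)

  set.seed(8)
  noisy <- tibble::tibble(measured_au = au,
                          true_area_mm2 = 0.002 * au + 0.5 + rnorm(5, 0, 0.3))
  cn <- fit_calibration(noisy)
  expect_equal(cn$residual_rmse,
               oracle_ols_rmse(noisy$measured_au, noisy$true_area_mm2),
               tolerance = 1e-10)

  falling <- tibble::tibble(measured_au = au, true_area_mm2 = rev(0.002 * au))
  expect_error(fit_calibration(falling), "non-positive slope")

  curve <- fit_calibration(exact)
  s <- grid_samples(3, pupil = c(1000, 2000, 3000))
  mm <- apply_calibration(s, curve)
  expect_equal(mm$pupil_mm2, c(2.5, 4.5, 6.5))
  expect_false("pupil_au" %in% names(mm))
})

test_that("preprocessing commutes with additive offsets and leaves change scores invariant", {
  cfg <- tiny_config(rate = 250, trials = 25, blocks = 1)
  tr <- ground_truth(calib_noise_au = 0)
  s <- simulate_session(cfg, tr, seed = 31)
  shifted <- s
  shifted$samples[[1]]$pupil_au <- shifted$samples[[1]]$pupil_au + 500

  a <- preprocess_session(s)
  b <- preprocess_session(shifted)
  expect_equal(b$samples[[1]]$pupil_mm2,
               a$samples[[1]]$pupil_mm2 + 500 * a$curve$slope,
               tolerance = 1e-8)
  ma <- compute_measures(a)
  mb <- compute_measures(b)
  expect_equal(mb$change, ma$change, tolerance = 1e-8)
})

test_that("peri-blink instability vanishes after margin masking and interpolation", {
  # constant trace + one blink with collapse ramps: after preprocessing the
  # block is constant again (no residual artifact survives the 200 ms margin)
  s <- grid_samples(3000, rate = 500, pupil = rep(1500, 3000))
  tr <- ground_truth()
  s <- inject_blinks(s, tr, blinks = tibble::tibble(start_ms = 2000,
                                                    duration_ms = 300))
  res <- preprocess_block(s, identity_curve())
  expect_lt(max(abs(res$samples$pupil_mm2 - mean(res$samples$pupil_mm2))),
            1e-6)
})

test_that("cleaning brings the trace closer to the noiseless ground truth than the raw recording", {
  cfg <- tiny_config(rate = 250, trials = 50, blocks = 1)
  tr <- clean_truth()
  ev <- plan_tones(cfg, 1, seed = 17)
  peaks <- c(standard = -0.6, oddball = 3, deviant = 1.1)
  truth_trace <- simulate_trace(ev, tr, cfg, peak_amps = peaks, noise = FALSE,
                                as_au = FALSE)
  set.seed(17)
  noisy <- truth_trace
  noisy$pupil_au <- noisy$pupil_mm2 + rnorm(nrow(noisy), 0, 0.1)
  noisy$pupil_mm2 <- NULL
  noisy$gaze_x_deg <- rep(0, nrow(noisy))
  noisy$gaze_y_deg <- rep(0, nrow(noisy))
  art <- inject_blinks(noisy, ground_truth(),
                       blinks = tibble::tibble(
                         start_ms = c(5000, 15000, 30000, 44000),
                         duration_ms = c(200, 350, 250, 300)
                       ))
  cleaned <- preprocess_block(art, identity_curve())$samples
  valid <- !is.na(art$pupil_au)
  r_raw <- cor(art$pupil_au[valid], truth_trace$pupil_mm2[valid])
  r_clean <- cor(cleaned$pupil_mm2, truth_trace$pupil_mm2)
  expect_gt(r_clean, r_raw)
})
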