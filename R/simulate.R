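#' Plan the tone sequence for one block
#'
#' Realises the tone mix as exact per-type counts (proportion x trials) in a
#' uniformly shuffled order, with onsets accumulated from inter-tone
#' intervals drawn uniformly from the configured jitter range. The standard
#' tone is 1400 Hz; oddball and deviant get 1600/1200 Hz according to the
#' config's counterbalance flag. Uses the current RNG state unless `seed` is
#' given.
#'
#' @param config A [session_config()].
#' @param block_index Which block (1-based); determines the reward label.
#' @param seed Optional integer; when given, seeds the RNG first.
#' @return Tibble with columns `onset_ms`, `trial_type`, `tone_hz`,
#'   `block_id`, `reward`.
#' @export
plan_tones <- function(config, block_index = 1L, seed = NULL) {
  validate_session_config(config)
  if (!is.null(seed)) set.seed(seed)
  n <- config$trials_per_block
  n_odd <- as.integer(round(n * config$p_oddball))
  n_dev <- as.integer(round(n * config$p_deviant))
  types <- c(
    rep("oddball", n_odd), rep("deviant", n_dev),
    rep("standard", n - n_odd - n_dev)
  )
  types <- sample(types)
  itis <- runif(n, config$iti_range_ms[1], config$iti_range_ms[2])
  onsets <- round(1000 + cumsum(itis))
  freqs <- if (config$counterbalance == "oddball_high") {
    c(standard = 1400, oddball = 1600, deviant = 1200)
  } else {
    c(standard = 1400, oddball = 1200, deviant = 1600)
  }
  tibble::tibble(
    onset_ms = as.numeric(onsets),
    trial_type = types,
    tone_hz = unname(freqs[types]),
    block_id = as.integer(block_index),
    reward = config$reward_schedule[block_index]
  )
}

# Surround a block's analysed tone sequence with warm-up / cool-down context
# tones (types drawn i.i.d. from the mix). They are simulated in the trace but
# never logged as trials, so the first and last analysed tones see the same
# neighbouring-response overlap as interior ones (the task runs continuously
# after a practice block, so boundary trials are not context-free).
with_context_tones <- function(events, config, n_pre = 4, n_post = 2) {
  probs <- c(
    standard = 1 - config$p_oddball - config$p_deviant,
    oddball = config$p_oddball,
    deviant = config$p_deviant
  )
  pre_iti <- runif(n_pre, config$iti_range_ms[1], config$iti_range_ms[2])
  post_iti <- runif(n_post, config$iti_range_ms[1], config$iti_range_ms[2])
  pre_on <- events$onset_ms[1] - rev(cumsum(pre_iti))
  shift <- max(0, 1000 - min(pre_on))
  events$onset_ms <- round(events$onset_ms + shift)
  pad <- tibble::tibble(
    onset_ms = round(c(pre_on + shift,
                       events$onset_ms[nrow(events)] + cumsum(post_iti))),
    trial_type = sample(names(probs), n_pre + n_post, replace = TRUE,
                        prob = probs),
    tone_hz = NA_real_,
    block_id = events$block_id[1],
    reward = events$reward[1]
  )
  all_events <- dplyr::arrange(dplyr::bind_rows(events, pad), .data$onset_ms)
  list(events = events, all_events = all_events)
}

# stationary AR(1) Gaussian noise; phi is the coefficient at the given
# sampling interval
ar1_noise <- function(n, sd, phi) {
  if (sd <= 0 || n == 0) return(numeric(n))
  innov <- rnorm(n, sd = sd * sqrt(1 - phi^2))
  innov[1] <- rnorm(1, sd = sd)
  as.numeric(stats::filter(innov, phi, method = "recursive"))
}

# rescale the reference AR(1) coefficient (defined at 500 Hz, i.e. per 2 ms)
# to the configured sampling interval so the autocorrelation time in ms is
# unchanged across rates
ar1_for_rate <- function(phi_ref, sampling_rate) {
  dt <- 1000 / sampling_rate
  phi_ref^(dt / 2)
}

#' Simulate a noiseless-to-noisy pupil trace for one block
#'
#' Builds the mm^2-scale signal `tonic + drift * t + sum_events peak * k(t -
#' onset) + AR(1) noise` on the block's sample grid, then (optionally) maps
#' it to tracker arbitrary units through the inverse of the ground-truth
#' calibration. Kernel peak amplitudes default to
#' [calibrate_amplitudes()] applied to the amplitude set of the block's
#' condition, so injected change-score amplitudes are recovered by the
#' analysis pipeline; pass `peak_amps` directly to bypass that calibration
#' (e.g. for superposition tests).
#'
#' @param events Event tibble from [plan_tones()], sorted by onset.
#' @param truth A [ground_truth()].
#' @param config A [session_config()].
#' @param condition Block condition label indexing amplitude set and tonic
#'   level (`"none"`, `"low"`, `"high"`, `"manual"`, `"counting"`).
#' @param peak_amps Optional named vector of kernel peak amplitudes (mm^2)
#'   per trial type, overriding the calibrated ones.
#' @param tonic Optional tonic level override (mm^2).
#' @param noise Logical; add AR(1) noise?
#' @param as_au Convert to arbitrary units? (`FALSE` returns mm^2.)
#' @param n_samples Optional sample count; defaults to covering the last
#'   event's full epoch window plus a 500 ms tail.
#' @return Tibble with `time_ms` and `pupil_au` (or `pupil_mm2`).
#' @export
simulate_trace <- function(events, truth, config, condition = "none",
                           peak_amps = NULL, tonic = NULL, noise = TRUE,
                           as_au = TRUE, n_samples = NULL) {
  dt <- 1000 / config$sampling_rate
  if (is.null(n_samples)) {
    end_ms <- max(events$onset_ms) + EPOCH_WINDOW_MS[2] + 500
    n_samples <- ceiling(end_ms / dt) + 1
  }
  t <- (seq_len(n_samples) - 1) * dt
  if (is.null(peak_amps)) {
    peak_amps <- calibrate_amplitudes(
      amp_for_condition(truth, condition), config, truth
    )
  }
  tonic <- tonic %||% tonic_for_condition(truth, condition)
  # drift is centred within the block (zero mean), so the tonic parameter
  # remains the block's mean level under mean-preserving detrending
  x <- tonic + truth$drift_slope_mm2_min / 60000 * (t - mean(t))
  support_ms <- EPOCH_WINDOW_MS[2] + 1000
  for (i in seq_len(nrow(events))) {
    on <- events$onset_ms[i]
    i0 <- floor(on / dt) + 1
    i1 <- min(ceiling((on + support_ms) / dt) + 1, n_samples)
    if (i0 > n_samples) next
    idx <- i0:i1
    x[idx] <- x[idx] + peak_amps[[events$trial_type[i]]] *
      pupil_kernel(t[idx] - on, truth$kernel_n, truth$kernel_tmax_ms)
  }
  if (noise && truth$noise_sd > 0) {
    x <- x + ar1_noise(n_samples, truth$noise_sd,
                       ar1_for_rate(truth$noise_ar1, config$sampling_rate))
  }
  if (as_au) {
    tibble::tibble(
      time_ms = t,
      pupil_au = (x - truth$calib_intercept) / truth$calib_slope
    )
  } else {
    tibble::tibble(time_ms = t, pupil_mm2 = x)
  }
}

#' Inject blinks and peri-blink instability into a sample stream
#'
#' Blink onsets arrive as a Poisson process at the ground-truth rate; each
#' blink replaces the pupil by the missing sentinel (`NA`) for a duration
#' drawn from the configured range, and in a ramp window immediately before
#' and after the recorded area collapses linearly toward the lid closure
#' (multiplicative factor dropping to 0.4 at the blink edge). The ramp is
#' narrower than the 200 ms masking margin preprocessing applies, so margin
#' extension removes the instability entirely.
#'
#' @param samples Sample tibble with `time_ms` and a pupil column.
#' @param truth A [ground_truth()].
#' @param blinks Optional tibble (`start_ms`, `duration_ms`) of blinks to
#'   inject deterministically instead of drawing them.
#' @return The samples with blinks applied; the realised blink table is
#'   attached as attribute `"blinks"`.
#' @export
inject_blinks <- function(samples, truth, blinks = NULL) {
  pupil_col <- intersect(c("pupil_au", "pupil_mm2"), names(samples))[1]
  t <- samples$time_ms
  dur_min <- (max(t) - min(t)) / 60000
  if (is.null(blinks)) {
    n_blinks <- rpois(1, truth$blink_rate_per_min * dur_min)
    blinks <- tibble::tibble(
      start_ms = sort(runif(n_blinks, min(t), max(t))),
      duration_ms = runif(n_blinks, truth$blink_duration_ms[1],
                          truth$blink_duration_ms[2])
    )
  }
  p <- samples[[pupil_col]]
  ramp <- truth$blink_ramp_ms
  for (i in seq_len(nrow(blinks))) {
    b0 <- blinks$start_ms[i]
    b1 <- b0 + blinks$duration_ms[i]
    p[t >= b0 & t < b1] <- NA_real_
    if (ramp > 0) {
      pre <- which(t >= b0 - ramp & t < b0)
      p[pre] <- p[pre] * (1 - 0.6 * (1 - (b0 - t[pre]) / ramp))
      post <- which(t >= b1 & t < b1 + ramp)
      p[post] <- p[post] * (1 - 0.6 * (1 - (t[post] - b1) / ramp))
    }
  }
  samples[[pupil_col]] <- p
  attr(samples, "blinks") <- blinks
  samples
}

#' Simulate gaze position around fixation
#'
#' Gaze follows a bounded mean-reverting random walk around the fixation
#' cross (stationary spread about 0.5 degrees, clamped inside 1.8 degrees),
#' plus occasional fixation-break excursions: at Poisson times the gaze jumps
#' 4-6 degrees away for 200-600 ms. Excursion intervals are returned so
#' tests can verify that the 2-degree preprocessing rule masks exactly those
#' samples.
#'
#' @param samples Sample tibble with `time_ms`.
#' @param truth A [ground_truth()].
#' @return The samples with `gaze_x_deg`/`gaze_y_deg` filled in; realised
#'   excursions (tibble `start_ms`, `end_ms`) attached as attribute
#'   `"excursions"`.
#' @export
simulate_gaze <- function(samples, truth) {
  t <- samples$time_ms
  n <- length(t)
  dt <- if (n > 1) t[2] - t[1] else 2
  rho <- exp(-dt / 200)
  s <- 0.5 * sqrt(1 - rho^2)
  x <- as.numeric(stats::filter(rnorm(n, sd = s), rho, method = "recursive"))
  y <- as.numeric(stats::filter(rnorm(n, sd = s), rho, method = "recursive"))
  r <- sqrt(x^2 + y^2)
  over <- r > 1.8
  x[over] <- x[over] * 1.8 / r[over]
  y[over] <- y[over] * 1.8 / r[over]

  dur_min <- (max(t) - min(t)) / 60000
  n_exc <- rpois(1, truth$gaze_excursion_rate_per_min * dur_min)
  excursions <- tibble::tibble(
    start_ms = sort(runif(n_exc, min(t), max(t))),
    duration_ms = runif(n_exc, 200, 600)
  )
  for (i in seq_len(nrow(excursions))) {
    idx <- t >= excursions$start_ms[i] &
      t < excursions$start_ms[i] + excursions$duration_ms[i]
    ang <- runif(1, 0, 2 * pi)
    mag <- runif(1, 4, 6)
    x[idx] <- x[idx] + mag * cos(ang)
    y[idx] <- y[idx] + mag * sin(ang)
  }
  samples$gaze_x_deg <- x
  samples$gaze_y_deg <- y
  attr(samples, "excursions") <- tibble::tibble(
    start_ms = excursions$start_ms,
    end_ms = excursions$start_ms + excursions$duration_ms
  )
  samples
}

#' Simulate manual responses to the tone sequence
#'
#' Oddball tones receive a response with probability `1 - miss rate`, with a
#' log-normal response time whose parameters depend on the block condition
#' (high reward speeds responses). Standard and deviant tones occasionally
#' attract spurious responses at their error rates. In counting blocks no
#' manual responses are produced.
#'
#' @param events Event tibble for one block.
#' @param truth A [ground_truth()].
#' @param config A [session_config()].
#' @param block_index Block number (for mode lookup).
#' @return The events with a `response_time_ms` column (`NA` = no response).
#' @export
simulate_behavior <- function(events, truth, config, block_index = 1L) {
  if (config$block_modes[block_index] == "counting") {
    events$response_time_ms <- NA_real_
    return(events)
  }
  cond <- events$reward[1]
  if (!cond %in% names(truth$rt_meanlog)) cond <- "none"
  n <- nrow(events)
  rts <- round(rlnorm(n, truth$rt_meanlog[cond], truth$rt_sdlog[cond]))
  respond <- ifelse(
    events$trial_type == "oddball",
    rbinom(n, 1, 1 - truth$error_rates["oddball"]) == 1,
    rbinom(n, 1, truth$error_rates[events$trial_type]) == 1
  )
  events$response_time_ms <- ifelse(respond, rts, NA_real_)
  events
}

#' Simulate a complete oddball session for one participant
#'
#' Draws participant-level deviations (tonic offset and per-type amplitude
#' deviations), then per block: plans the tone sequence, synthesises the
#' pupil trace (phasic responses on a tonic + drift + AR(1)-noise background,
#' expressed in tracker units), adds gaze wander and excursions, injects
#' blinks, and simulates manual responses. A calibration table of
#' artificial-pupil readings (known areas for 2-8 mm disc diameters, measured
#' in au with small noise) is generated alongside.
#'
#' @param config A [session_config()].
#' @param truth A [ground_truth()].
#' @param participant_id Participant label.
#' @param seed Integer seed; defaults to the config's.
#' @return A `pupil_session`: list with `samples` (one tibble per block:
#'   `time_ms`, `gaze_x_deg`, `gaze_y_deg`, `pupil_au`), `events` (all
#'   blocks), `calibration`, `config`, `truth`, `participant_id`, and
#'   `realized` (participant draws and artifact intervals, for recovery
#'   tests).
#' @export
simulate_session <- function(config, truth, participant_id = "p01",
                             seed = config$seed) {
  validate_session_config(config)
  validate_ground_truth(truth)
  set.seed(seed)

  tonic_dev <- rnorm(1, 0, truth$tonic_sd)
  amp_dev <- rnorm(length(TRIAL_TYPES), 0, truth$amp_sd[TRIAL_TYPES])
  names(amp_dev) <- TRIAL_TYPES

  samples <- vector("list", config$n_blocks)
  events <- vector("list", config$n_blocks)
  realized_blinks <- vector("list", config$n_blocks)
  realized_exc <- vector("list", config$n_blocks)

  for (b in seq_len(config$n_blocks)) {
    cond <- block_condition(config, b)
    ctx <- with_context_tones(plan_tones(config, b), config)
    ev <- ctx$events
    amps_i <- amp_for_condition(truth, cond) + amp_dev
    peaks <- calibrate_amplitudes(amps_i, config, truth)
    # tonic_level is specified on the measured-baseline scale: subtract the
    # expected phasic leakage into the baseline window so the pipeline's
    # baseline means are centred on the injected values
    tonic_i <- tonic_for_condition(truth, cond) + tonic_dev -
      attr(peaks, "baseline_leakage")
    tr <- simulate_trace(ctx$all_events, truth, config, condition = cond,
                         peak_amps = peaks, tonic = tonic_i)
    tr <- simulate_gaze(tr, truth)
    realized_exc[[b]] <- attr(tr, "excursions")
    tr <- inject_blinks(tr, truth)
    realized_blinks[[b]] <- attr(tr, "blinks")
    ev <- simulate_behavior(ev, truth, config, b)
    blk <- tr[, c("time_ms", "gaze_x_deg", "gaze_y_deg", "pupil_au")]
    attr(blk, "blinks") <- NULL
    attr(blk, "excursions") <- NULL
    samples[[b]] <- blk
    events[[b]] <- ev
  }

  calib_true <- pi * (seq(2, 8, by = 1) / 2)^2
  calibration <- tibble::tibble(
    measured_au = (calib_true - truth$calib_intercept) / truth$calib_slope +
      rnorm(length(calib_true), 0, truth$calib_noise_au),
    true_area_mm2 = calib_true
  )

  structure(
    list(
      participant_id = participant_id,
      samples = samples,
      events = dplyr::bind_rows(events),
      calibration = calibration,
      config = config,
      truth = truth,
      realized = list(
        tonic_dev = tonic_dev,
        amp_dev = amp_dev,
        blinks = realized_blinks,
        excursions = realized_exc,
        seed = seed
      )
    ),
    class = "pupil_session"
  )
}

#' @export
print.pupil_session <- function(x, ...) {
  cat(sprintf(
    "<pupil_session> %s: %d block(s), %d events, %d samples/block\n",
    x$participant_id, x$config$n_blocks, nrow(x$events),
    nrow(x$samples[[1]])
  ))
  invisible(x)
}

#' Simulate a whole study
#'
#' Generates `n_participants` sessions under one of the preset designs (or a
#' caller-supplied config/truth pair), counterbalancing the oddball tone
#' assignment and the block-condition order across participants, with
#' per-participant seeds derived from the master seed.
#'
#' @param experiment Preset name passed to [default_design()], or `NULL` when
#'   `config`/`truth` are given.
#' @param n_participants Number of simulated participants.
#' @param seed Master seed.
#' @param config,truth Optional explicit design, overriding the preset.
#' @param sampling_rate,trials_per_block Scale-down overrides forwarded to
#'   [default_design()].
#' @return List of `pupil_session` objects.
#' @export
simulate_study <- function(experiment = "exp1", n_participants = 24,
                           seed = 1L, config = NULL, truth = NULL,
                           sampling_rate = 500, trials_per_block = NULL) {
  if (is.null(config) || is.null(truth)) {
    d <- default_design(experiment, sampling_rate = sampling_rate,
                        trials_per_block = trials_per_block, seed = seed)
    config <- config %||% d$config
    truth <- truth %||% d$truth
  }
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_participants)
  lapply(seq_len(n_participants), function(i) {
    cfg_i <- config
    cfg_i$counterbalance <- if (i %% 2 == 1) "oddball_high" else "oddball_low"
    if (i %% 4 >= 2) {
      cfg_i$reward_schedule <- rev(cfg_i$reward_schedule)
      cfg_i$block_modes <- rev(cfg_i$block_modes)
    }
    simulate_session(cfg_i, truth, participant_id = sprintf("p%02d", i),
                     seed = seeds[i])
  })
}

#' Simulate trial-level change scores directly
#'
#' Lightweight generator that emulates the distribution of the pipeline's
#' per-trial change scores without synthesising sample streams: change =
#' cell amplitude + participant deviation + trial residual. Used for
#' Monte-Carlo studies of the statistical layer (parameter recovery, random
#' structure selection, familywise error control), where thousands of
#' replicates must fit in seconds.
#'
#' @param n_participants Number of participants.
#' @param n_trials Trials per participant per condition (split 84/8/8 across
#'   types, exact counts).
#' @param amp Amplitude sets as in [ground_truth()]: a named per-type vector,
#'   or a list of them keyed by condition label.
#' @param amp_sd Named per-type vector of between-participant amplitude sds.
#' @param resid_sd Trial-level residual sd of the change score (mm^2).
#' @param baseline_mean,tonic_sd,baseline_resid_sd Tonic level per condition
#'   (named vector), its between-participant sd, and the trial-level sd of
#'   the baseline epoch mean.
#' @param seed Integer seed.
#' @return Tibble with `participant`, `reward`, `trial_type`, `change`,
#'   `baseline_mean`.
#' @export
simulate_change_scores <- function(n_participants = 20, n_trials = 125,
                                   amp = c(standard = -0.283, oddball = 1.403,
                                           deviant = 0.535),
                                   amp_sd = c(standard = 0.2, oddball = 1.0,
                                              deviant = 0.6),
                                   resid_sd = 0.55,
                                   baseline_mean = c(none = 15),
                                   tonic_sd = 5, baseline_resid_sd = 0.4,
                                   seed = 1L) {
  set.seed(seed)
  amp <- normalise_amp(amp)
  conditions <- names(amp)
  n_odd <- round(0.08 * n_trials)
  types <- c(rep("standard", n_trials - 2 * n_odd),
             rep("oddball", n_odd), rep("deviant", n_odd))
  out <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    u <- rnorm(3, 0, amp_sd[TRIAL_TYPES])
    names(u) <- TRIAL_TYPES
    tonic_i <- rnorm(1, 0, tonic_sd)
    rows <- lapply(conditions, function(cond) {
      a <- amp[[cond]]
      tt <- sample(types)
      tibble::tibble(
        participant = sprintf("p%02d", i),
        reward = cond,
        trial_type = tt,
        change = unname(a[tt] + u[tt]) + rnorm(n_trials, 0, resid_sd),
        baseline_mean = unname(
          baseline_mean[if (cond %in% names(baseline_mean)) cond else 1]
        ) + tonic_i + rnorm(n_trials, 0, baseline_resid_sd)
      )
    })
    out[[i]] <- dplyr::bind_rows(rows)
  }
  dplyr::bind_rows(out)
}
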