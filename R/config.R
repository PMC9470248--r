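#' Session configuration for the oddball simulator
#'
#' Describes one participant session of the auditory oddball task: block
#' structure, tone mix, timing, and (for reward experiments) the per-block
#' reward schedule. Defaults follow the task as run in the experiments the
#' package emulates: 100 ms tones, an 8% oddball and an 8% deviant among 84%
#' standards, inter-tone intervals jittered uniformly between 1.2 and 1.7 s,
#' and 500 Hz pupil sampling.
#'
#' Per-type tone counts must be whole numbers (`trials_per_block * p_oddball`
#' etc.); the simulator realises the mix as exact counts in shuffled order,
#' not independent draws, so a 50-trial block holds exactly 4 oddballs.
#'
#' @param sampling_rate Samples per second. Must divide 1000 so that the
#'   sample grid falls on integer milliseconds.
#' @param n_blocks Number of experimental blocks.
#' @param trials_per_block Tones per block.
#' @param p_oddball,p_deviant Proportion of oddball / deviant tones.
#' @param tone_duration_ms Tone duration (ms).
#' @param iti_range_ms Length-2 numeric, uniform jitter bounds (ms) for the
#'   inter-tone interval.
#' @param reward_schedule Character vector, one label per block, each one of
#'   `"low"`, `"high"`, `"none"`.
#' @param block_modes Character vector, one of `"manual"`/`"counting"` per
#'   block. Counting blocks collect no manual responses.
#' @param response_deadline_ms Deadline (ms) for a rewarded response, or `NA`
#'   when no deadline applies.
#' @param counterbalance `"oddball_high"` assigns the 1600 Hz tone to the
#'   oddball and 1200 Hz to the deviant; `"oddball_low"` swaps them. The
#'   standard is always 1400 Hz.
#' @param seed Integer seed stored with the config; every simulation that
#'   takes this config is deterministic given it.
#' @return An object of class `session_config` (a validated list).
#' @examples
#' cfg <- session_config(n_blocks = 2, trials_per_block = 250)
#' cfg$trials_per_block * cfg$p_oddball # exactly 20 oddballs per block
#' @export
session_config <- function(sampling_rate = 500,
                           n_blocks = 2,
                           trials_per_block = 250,
                           p_oddball = 0.08,
                           p_deviant = 0.08,
                           tone_duration_ms = 100,
                           iti_range_ms = c(1200, 1700),
                           reward_schedule = rep("none", n_blocks),
                           block_modes = rep("manual", n_blocks),
                           response_deadline_ms = NA_real_,
                           counterbalance = c("oddball_high", "oddball_low"),
                           seed = 1L) {
  counterbalance <- match.arg(counterbalance)
  cfg <- structure(
    list(
      sampling_rate = sampling_rate,
      n_blocks = as.integer(n_blocks),
      trials_per_block = as.integer(trials_per_block),
      p_oddball = p_oddball,
      p_deviant = p_deviant,
      tone_duration_ms = tone_duration_ms,
      iti_range_ms = as.numeric(iti_range_ms),
      reward_schedule = reward_schedule,
      block_modes = block_modes,
      response_deadline_ms = response_deadline_ms,
      counterbalance = counterbalance,
      seed = as.integer(seed)
    ),
    class = "session_config"
  )
  validate_session_config(cfg)
}

validate_session_config <- function(cfg) {
  stopifnot(inherits(cfg, "session_config"))
  if (cfg$sampling_rate <= 0 || 1000 %% cfg$sampling_rate != 0) {
    abort("`sampling_rate` must be positive and divide 1000 (e.g. 500, 250, 100).")
  }
  if (cfg$p_oddball < 0 || cfg$p_deviant < 0 ||
      cfg$p_oddball + cfg$p_deviant >= 1) {
    abort("tone proportions must satisfy p_oddball + p_deviant < 1.")
  }
  n_odd <- cfg$trials_per_block * cfg$p_oddball
  n_dev <- cfg$trials_per_block * cfg$p_deviant
  if (abs(n_odd - round(n_odd)) > 1e-8 || abs(n_dev - round(n_dev)) > 1e-8) {
    abort(paste0(
      "trials_per_block x p_oddball and x p_deviant must be integers; got ",
      format(n_odd), " and ", format(n_dev), "."
    ))
  }
  if (length(cfg$iti_range_ms) != 2 || cfg$iti_range_ms[1] >= cfg$iti_range_ms[2]) {
    abort("`iti_range_ms` must be c(min, max) with min < max.")
  }
  if (length(cfg$reward_schedule) != cfg$n_blocks ||
      !all(cfg$reward_schedule %in% REWARD_LEVELS)) {
    abort("`reward_schedule` needs one of low/high/none per block.")
  }
  if (length(cfg$block_modes) != cfg$n_blocks ||
      !all(cfg$block_modes %in% RESPONSE_MODES)) {
    abort("`block_modes` needs one of manual/counting per block.")
  }
  cfg
}

#' @export
print.session_config <- function(x, ...) {
  cat("<session_config>\n")
  cat(sprintf(
    "  %d block(s) x %d trials @ %g Hz; oddball %g%%, deviant %g%%\n",
    x$n_blocks, x$trials_per_block, x$sampling_rate,
    100 * x$p_oddball, 100 * x$p_deviant
  ))
  cat(sprintf(
    "  ITI %g-%g ms; rewards: %s; modes: %s; seed %d\n",
    x$iti_range_ms[1], x$iti_range_ms[2],
    paste(x$reward_schedule, collapse = ","),
    paste(x$block_modes, collapse = ","), x$seed
  ))
  invisible(x)
}

#' Ground truth parameters for the simulator
#'
#' Collects every generative parameter of a synthetic session: tonic pupil
#' level per reward condition, slow within-block drift, phasic amplitudes per
#' (trial type, condition) cell, the response-kernel shape, AR(1) measurement
#' noise, blink and gaze-excursion artifact rates, behavioural error rates and
#' response-time distributions, and the affine map between the tracker's
#' arbitrary units and mm^2.
#'
#' Amplitudes are given on the scale of the *measured change score* (mean
#' pupil area over 500-2000 ms post-onset minus the -500-0 ms baseline, mm^2):
#' the simulator internally converts them to kernel peak amplitudes by
#' inverting the epoch-window gain and the expected overlap from neighbouring
#' trials, so a cell simulated with `amp = 1.4` yields change scores centred
#' on 1.4 mm^2. A negative standard amplitude encodes habituation (a small
#' constriction to the frequent tone).
#'
#' Participant heterogeneity is controlled by `tonic_sd` (between-participant
#' sd of the tonic level) and `amp_sd` (between-participant sd of each
#' trial-type amplitude); both feed the random-effect structure the analysis
#' models estimate.
#'
#' @param amp Named list / vector of change-score amplitudes (mm^2). Either
#'   one value per trial type (`standard`, `oddball`, `deviant`) or, for
#'   condition-dependent effects, a list with one such vector per condition
#'   label.
#' @param tonic_level Named vector of tonic pupil area (mm^2) per condition
#'   label appearing in the schedule (`low`, `high`, `none`, or response
#'   modes).
#' @param drift_slope_mm2_min Linear drift in mm^2 per minute within a block.
#' @param kernel_n,kernel_tmax_ms Shape and time-to-peak of the pupil
#'   response kernel.
#' @param noise_sd Stationary sd (mm^2) of the AR(1) measurement noise.
#' @param noise_ar1 AR(1) coefficient of the noise at 500 Hz; rescaled as
#'   `noise_ar1^(dt/2)` at other sampling intervals so the autocorrelation
#'   time is rate-invariant.
#' @param tonic_sd Between-participant sd of the tonic level (mm^2).
#' @param amp_sd Named vector, between-participant sd of each trial-type
#'   amplitude (mm^2).
#' @param blink_rate_per_min Blink onsets per minute (Poisson).
#' @param blink_duration_ms Length-2 range of blink durations.
#' @param blink_ramp_ms Width of the pre/post-blink instability ramp during
#'   which the recorded area collapses; kept below the 200 ms masking margin
#'   the preprocessing applies.
#' @param gaze_excursion_rate_per_min Fixation-break excursions per minute.
#' @param error_rates Named vector: miss probability for oddballs, spurious
#'   response probabilities for standards and deviants.
#' @param rt_meanlog,rt_sdlog Named vectors of log-normal RT parameters per
#'   condition label.
#' @param calib_slope,calib_intercept Affine map mm^2 = slope * au + intercept
#'   used in reverse to express simulated traces in tracker units.
#' @param calib_noise_au Measurement noise (au) on the artificial-pupil
#'   calibration readings.
#' @return An object of class `ground_truth` (a validated list).
#' @seealso [default_ground_truth()] for presets matching the three
#'   experiment designs.
#' @export
ground_truth <- function(amp = list(
                           standard = -0.283, oddball = 1.403, deviant = 0.535
                         ),
                         tonic_level = c(low = 15.1, high = 15.8, none = 15.0),
                         drift_slope_mm2_min = -0.3,
                         kernel_n = 10.1,
                         kernel_tmax_ms = 930,
                         noise_sd = 0.5,
                         noise_ar1 = 0.97,
                         tonic_sd = 5.0,
                         amp_sd = c(standard = 0.2, oddball = 1.0, deviant = 0.6),
                         blink_rate_per_min = 10,
                         blink_duration_ms = c(100, 400),
                         blink_ramp_ms = 120,
                         gaze_excursion_rate_per_min = 2,
                         error_rates = c(oddball = 0.05, standard = 0.01,
                                         deviant = 0.02),
                         rt_meanlog = c(low = log(690) - 0.02,
                                        high = log(670) - 0.02,
                                        none = log(500) - 0.02),
                         rt_sdlog = c(low = 0.2, high = 0.2, none = 0.2),
                         calib_slope = 0.002,
                         calib_intercept = 0.5,
                         calib_noise_au = 2) {
  truth <- structure(
    list(
      amp = normalise_amp(amp),
      tonic_level = tonic_level,
      drift_slope_mm2_min = drift_slope_mm2_min,
      kernel_n = kernel_n,
      kernel_tmax_ms = kernel_tmax_ms,
      noise_sd = noise_sd,
      noise_ar1 = noise_ar1,
      tonic_sd = tonic_sd,
      amp_sd = amp_sd,
      blink_rate_per_min = blink_rate_per_min,
      blink_duration_ms = blink_duration_ms,
      blink_ramp_ms = blink_ramp_ms,
      gaze_excursion_rate_per_min = gaze_excursion_rate_per_min,
      error_rates = error_rates,
      rt_meanlog = rt_meanlog,
      rt_sdlog = rt_sdlog,
      calib_slope = calib_slope,
      calib_intercept = calib_intercept,
      calib_noise_au = calib_noise_au
    ),
    class = "ground_truth"
  )
  validate_ground_truth(truth)
}

# amp may be a single per-type vector or a per-condition list of them;
# normalise to a named list of named numeric vectors
normalise_amp <- function(amp) {
  if (is.numeric(amp) && !is.null(names(amp))) {
    amp <- list(none = amp)
  } else if (is.list(amp) && all(TRIAL_TYPES %in% names(amp))) {
    amp <- list(none = unlist(amp))
  }
  amp <- lapply(amp, function(a) {
    a <- unlist(a)
    if (!all(TRIAL_TYPES %in% names(a))) {
      abort("each amplitude set needs named entries standard/oddball/deviant.")
    }
    a[TRIAL_TYPES]
  })
  amp
}

validate_ground_truth <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  if (any(truth$tonic_level <= 0)) abort("tonic levels must be positive.")
  if (any(truth$error_rates < 0 | truth$error_rates > 1)) {
    abort("error rates must lie in [0, 1].")
  }
  if (truth$noise_ar1 < 0 || truth$noise_ar1 >= 1) {
    abort("noise_ar1 must lie in [0, 1).")
  }
  if (truth$kernel_n <= 0 || truth$kernel_tmax_ms <= 0) {
    abort("kernel parameters must be positive.")
  }
  if (truth$calib_slope <= 0) abort("calib_slope must be positive.")
  truth
}

# amplitude set for a block condition label, falling back to the only set
amp_for_condition <- function(truth, condition) {
  if (condition %in% names(truth$amp)) {
    truth$amp[[condition]]
  } else if (length(truth$amp) == 1) {
    truth$amp[[1]]
  } else {
    abort(paste0("no amplitude set for condition '", condition, "'."))
  }
}

tonic_for_condition <- function(truth, condition) {
  if (condition %in% names(truth$tonic_level)) {
    unname(truth$tonic_level[condition])
  } else {
    unname(truth$tonic_level[1])
  }
}

#' Preset study designs and generative parameters
#'
#' Returns the `session_config` and `ground_truth` matching one of the three
#' experiment designs the package emulates: a plain oddball task (two 250-trial
#' blocks, manual responses), a manual-versus-counting manipulation (four
#' 125-trial blocks), or a low/high reward manipulation (four 125-trial blocks
#' with a 0.7 s response deadline). Phasic amplitudes, tonic levels and
#' response-time parameters are set to the marginal means the corresponding
#' experiments report, so a simulated study is centred on the published
#' effect pattern.
#'
#' @param experiment `"exp1"`, `"exp2"` or `"exp3"`.
#' @param sampling_rate,trials_per_block Optional overrides used to scale
#'   simulations down (e.g. in examples and tests).
#' @param seed Integer seed stored in the config.
#' @return List with elements `config` and `truth`.
#' @examples
#' d <- default_design("exp1", trials_per_block = 25, sampling_rate = 100)
#' d$truth$amp$none
#' @export
default_design <- function(experiment = c("exp1", "exp2", "exp3"),
                           sampling_rate = 500,
                           trials_per_block = NULL,
                           seed = 1L) {
  experiment <- match.arg(experiment)
  switch(experiment,
    exp1 = {
      tpb <- trials_per_block %||% 250L
      list(
        config = session_config(
          sampling_rate = sampling_rate, n_blocks = 2, trials_per_block = tpb,
          reward_schedule = rep("none", 2), block_modes = rep("manual", 2),
          seed = seed
        ),
        truth = ground_truth(
          amp = c(standard = -0.283, oddball = 1.403, deviant = 0.535),
          tonic_level = c(none = 15.0)
        )
      )
    },
    exp2 = {
      tpb <- trials_per_block %||% 125L
      list(
        config = session_config(
          sampling_rate = sampling_rate, n_blocks = 4, trials_per_block = tpb,
          reward_schedule = rep("none", 4),
          block_modes = c("manual", "manual", "counting", "counting"),
          seed = seed
        ),
        truth = ground_truth(
          amp = list(
            manual = c(standard = -0.22, oddball = 0.83, deviant = 0.47),
            counting = c(standard = -0.30, oddball = 0.75, deviant = 0.39)
          ),
          tonic_level = c(manual = 15.0, counting = 15.0, none = 15.0)
        )
      )
    },
    exp3 = {
      tpb <- trials_per_block %||% 125L
      list(
        config = session_config(
          sampling_rate = sampling_rate, n_blocks = 4, trials_per_block = tpb,
          reward_schedule = c("low", "high", "low", "high"),
          block_modes = rep("manual", 4),
          response_deadline_ms = 700,
          seed = seed
        ),
        truth = ground_truth(
          amp = list(
            low = c(standard = -0.089, oddball = 2.029, deviant = 0.549),
            high = c(standard = -0.047, oddball = 2.527, deviant = 0.492)
          ),
          tonic_level = c(low = 15.135, high = 15.866)
        )
      )
    }
  )
}

#' @rdname default_design
#' @export
default_ground_truth <- function(experiment = c("exp1", "exp2", "exp3")) {
  default_design(match.arg(experiment))$truth
}

# block condition label used to index amplitudes / tonic levels:
# reward label for reward designs, response mode for mode designs
block_condition <- function(cfg, block_index) {
  rw <- cfg$reward_schedule[block_index]
  if (rw != "none") rw else if (cfg$block_modes[block_index] == "counting") {
    "counting"
  } else if (any(cfg$block_modes == "counting")) {
    "manual"
  } else {
    "none"
  }
}
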