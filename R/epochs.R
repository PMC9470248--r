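#' Extract per-trial epochs from a cleaned block
#'
#' Cuts the cleaned, calibrated trace into trial epochs time-locked to tone
#' onsets, spanning -500 ms to +4000 ms around the onset (half-open; 2250
#' samples at 500 Hz, 250 of them pre-onset). The onset is aligned to the
#' nearest sample at or after the event time. Epochs that would overlap a
#' block edge are dropped with a warning; overlap between consecutive epochs
#' is permitted.
#'
#' @param samples Cleaned sample tibble for one block (`pupil_mm2`, and
#'   optionally `interpolated`).
#' @param events Event tibble for that block.
#' @param rate Sampling rate (Hz).
#' @return List: `epochs` — a matrix (samples x trials) of pupil values,
#'   with attribute `"interpolated"` holding per-trial interpolated
#'   fractions; `events` — the events retained; `n_dropped` — events lost
#'   at block edges.
#' @export
extract_epochs <- function(samples, events, rate) {
  dt <- 1000 / rate
  n <- nrow(samples)
  t0 <- samples$time_ms[1]
  n_pre <- as.integer(-EPOCH_WINDOW_MS[1] / dt)
  n_total <- as.integer(diff(EPOCH_WINDOW_MS) / dt)
  onset_idx <- ceiling((events$onset_ms - t0) / dt) + 1L
  first <- onset_idx - n_pre
  last <- first + n_total - 1L
  keep <- first >= 1L & last <= n
  if (any(!keep)) {
    warn(sprintf("dropping %d epoch(s) overlapping block edges.", sum(!keep)))
  }
  kept_first <- first[keep]
  idx <- outer(seq_len(n_total) - 1L, kept_first, `+`)
  epochs <- matrix(samples$pupil_mm2[idx], nrow = n_total)
  if ("interpolated" %in% names(samples)) {
    fi <- colMeans(matrix(samples$interpolated[idx], nrow = n_total))
  } else {
    fi <- rep(0, sum(keep))
  }
  attr(epochs, "interpolated") <- fi
  list(epochs = epochs, events = events[keep, , drop = FALSE],
       n_dropped = sum(!keep))
}

#' Score trials: baseline mean, response mean, change
#'
#' Averages each epoch over the pre-stimulus baseline window (-500-0 ms) and
#' the stimulus response window (500-2000 ms); the primary dependent measure
#' is their difference, the *change in pupil response*. Both windows are
#' half-open on the shared sample grid.
#'
#' @param epochs Epoch matrix from [extract_epochs()] (or a single epoch
#'   vector).
#' @param rate Sampling rate (Hz).
#' @return Tibble with `baseline_mean`, `response_mean`, `change` (mm^2),
#'   one row per trial.
#' @export
score_trial <- function(epochs, rate) {
  if (is.null(dim(epochs))) epochs <- matrix(epochs, ncol = 1)
  dt <- 1000 / rate
  rel <- function(ms) as.integer((ms - EPOCH_WINDOW_MS[1]) / dt)
  base_idx <- (rel(BASELINE_WINDOW_MS[1]) + 1L):rel(BASELINE_WINDOW_MS[2])
  resp_idx <- (rel(RESPONSE_WINDOW_MS[1]) + 1L):rel(RESPONSE_WINDOW_MS[2])
  baseline <- colMeans(epochs[base_idx, , drop = FALSE])
  response <- colMeans(epochs[resp_idx, , drop = FALSE])
  tibble::tibble(
    baseline_mean = baseline,
    response_mean = response,
    change = response - baseline
  )
}

#' Classify trial outcomes
#'
#' An oddball without a manual response is an error (miss); a standard or
#' deviant with a manual response is an error (false alarm); everything else
#' is correct. In counting blocks no manual-response criterion applies, so
#' all trials are correct at the trial level. Responses slower than a reward
#' deadline still count as responses: the deadline affects feedback and
#' reward, not trial validity.
#'
#' @param events Event tibble (with `response_time_ms`).
#' @param mode `"manual"` or `"counting"` (scalar or per-event vector).
#' @return Character vector `"correct"`/`"error"` per event.
#' @export
classify_outcome <- function(events, mode = "manual") {
  responded <- !is.na(events$response_time_ms)
  out <- ifelse(
    events$trial_type == "oddball", ifelse(responded, "correct", "error"),
    ifelse(responded, "error", "correct")
  )
  out[rep_len(mode, nrow(events)) == "counting"] <- "correct"
  out
}

#' Compute per-trial measures for one session
#'
#' Runs epoch extraction and scoring over every block of a preprocessed
#' session and assembles the per-trial measures table the statistical models
#' consume.
#'
#' @param session A preprocessed `pupil_session` (see
#'   [preprocess_session()]).
#' @return Tibble with columns `participant`, `block_id`, `trial`,
#'   `trial_type`, `reward`, `response_mode`, `outcome`, `baseline_mean`,
#'   `response_mean`, `change`, `rt_ms`, `fraction_interpolated`.
#' @export
compute_measures <- function(session) {
  rate <- session$config$sampling_rate
  rows <- lapply(seq_along(session$samples), function(b) {
    ev_b <- session$events[session$events$block_id == b, , drop = FALSE]
    if (nrow(ev_b) == 0) return(NULL)
    ex <- extract_epochs(session$samples[[b]], ev_b, rate)
    sc <- score_trial(ex$epochs, rate)
    mode_b <- session$config$block_modes[b]
    tibble::tibble(
      participant = session$participant_id,
      block_id = b,
      trial = seq_len(nrow(ex$events)),
      trial_type = ex$events$trial_type,
      reward = ex$events$reward,
      response_mode = mode_b,
      outcome = classify_outcome(ex$events, mode_b),
      baseline_mean = sc$baseline_mean,
      response_mean = sc$response_mean,
      change = sc$change,
      rt_ms = ex$events$response_time_ms,
      fraction_interpolated = attr(ex$epochs, "interpolated")
    )
  })
  dplyr::bind_rows(rows)
}

#' Apply the error-based exclusion rules
#'
#' Error trials are removed from the pupil analysis, and participants whose
#' overall error rate is strictly greater than the cutoff (default 20%) are
#' removed entirely.
#'
#' @param measures Per-trial measures (possibly several participants).
#' @param max_error_rate Participant-level exclusion cutoff (strict
#'   inequality).
#' @return List: `measures` (filtered), `report` (per-participant error
#'   rates and exclusion flags, plus trial counts removed).
#' @export
apply_exclusions <- function(measures, max_error_rate = 0.20) {
  rates <- measures |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      n_errors = sum(.data$outcome == "error"),
      error_rate = .data$n_errors / .data$n_trials,
      .groups = "drop"
    ) |>
    dplyr::mutate(excluded = .data$error_rate > max_error_rate)
  excluded_ids <- rates$participant[rates$excluded]
  kept <- measures |>
    dplyr::filter(!.data$participant %in% excluded_ids,
                  .data$outcome == "correct")
  list(
    measures = kept,
    report = list(
      participants = rates,
      n_participants_excluded = length(excluded_ids),
      n_error_trials_removed = sum(
        measures$outcome == "error" &
          !measures$participant %in% excluded_ids
      )
    )
  )
}
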