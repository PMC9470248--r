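#' Canonical pupil response kernel
#'
#' Unit-peak Erlang-family impulse response used for the phasic,
#' stimulus-locked component of the simulated pupil signal:
#' `k(t) = (t/tmax)^n * exp(n * (1 - t/tmax))`, which rises from 0 at onset
#' to 1 at `t = tmax` and decays smoothly afterwards. With the default shape
#' (`n = 10.1`, `tmax = 930` ms) the response peaks just before 1 s and has
#' essentially returned to zero by 3 s, the morphology typical of
#' event-related pupil dilations.
#'
#' @param t_ms Time since event onset, ms (vectorised). Values `< 0` return 0.
#' @param n Dimensionless shape parameter (> 0).
#' @param tmax_ms Time-to-peak, ms (> 0).
#' @return Numeric vector of kernel values in `[0, 1]`.
#' @examples
#' pupil_kernel(930) # 1 at the peak
#' pupil_kernel(0)   # 0 at onset
#' @export
pupil_kernel <- function(t_ms, n = 10.1, tmax_ms = 930) {
  stopifnot(n > 0, tmax_ms > 0)
  r <- t_ms / tmax_ms
  out <- numeric(length(r))
  pos <- which(r > 0)
  # log-space to avoid overflow of r^n for large n
  out[pos] <- exp(n * (log(r[pos]) + 1 - r[pos]))
  out
}

# Mean kernel value over the response window minus the baseline window,
# evaluated on the sample grid: the factor by which a kernel peak amplitude
# shows up in the change score of an isolated trial.
kernel_window_gain <- function(n = 10.1, tmax_ms = 930, sampling_rate = 500) {
  dt <- 1000 / sampling_rate
  t_resp <- seq(RESPONSE_WINDOW_MS[1], RESPONSE_WINDOW_MS[2] - dt, by = dt)
  t_base <- seq(BASELINE_WINDOW_MS[1], BASELINE_WINDOW_MS[2] - dt, by = dt)
  mean(pupil_kernel(t_resp, n, tmax_ms)) - mean(pupil_kernel(t_base, n, tmax_ms))
}

# Expected contribution of neighbouring trials to a trial's epoch windows per
# unit of (mixture-average) kernel peak amplitude, under the steady-state ITI
# distribution. Computed by deterministic numeric convolution on a 1 ms grid:
# the lag to the m-th previous/next tone is a sum of m iid Uniform(iti) draws.
# A past neighbour at lag L adds k(t + L) to the trace at epoch time t; a
# future neighbour adds k(t - L) where k vanishes for negative arguments.
# Returns the response-window and baseline-window leakage separately: with
# ITIs shorter than the kernel support the baseline window sits near the
# previous response's peak, so the baseline term dominates and the net
# change-score coefficient (resp - base) is negative.
overlap_components <- function(n = 10.1, tmax_ms = 930,
                               iti_range_ms = c(1200, 1700),
                               max_neighbours = 4) {
  dt <- 1
  t_max <- ceiling(max_neighbours * iti_range_ms[2] + RESPONSE_WINDOW_MS[2])
  tk <- seq(0, t_max, by = dt)
  k <- pupil_kernel(tk, n, tmax_ms)
  csum <- cumsum(k) * dt

  # mean of k over [a, b) in ms (a, b >= 0), via the cumulative integral
  window_mean <- function(a, b) {
    a <- pmax(a, 0); b <- pmax(b, 0)
    ia <- pmin(round(a) + 1, length(csum))
    ib <- pmin(round(b) + 1, length(csum))
    (csum[ib] - csum[ia]) / (b - a)
  }

  # density of the lag to the m-th neighbour on the 1 ms grid, by convolution
  iti_grid <- seq(ceiling(iti_range_ms[1]), floor(iti_range_ms[2]), by = dt)
  d1 <- rep(1 / length(iti_grid), length(iti_grid))
  lag_density <- d1
  lag_start <- iti_grid[1]

  kappa_resp <- 0
  kappa_base <- 0
  for (m in seq_len(max_neighbours)) {
    lags <- lag_start + dt * (seq_along(lag_density) - 1)
    # past neighbour m steps back
    resp_past <- window_mean(lags + RESPONSE_WINDOW_MS[1], lags + RESPONSE_WINDOW_MS[2])
    base_past <- window_mean(lags + BASELINE_WINDOW_MS[1], lags + BASELINE_WINDOW_MS[2])
    kappa_resp <- kappa_resp + sum(lag_density * resp_past)
    kappa_base <- kappa_base + sum(lag_density * base_past)
    # future neighbour m steps ahead: k(t - L) over t in the response window
    lo <- pmax(RESPONSE_WINDOW_MS[1] - lags, 0)
    hi <- pmax(RESPONSE_WINDOW_MS[2] - lags, 0)
    resp_fut <- ifelse(hi > lo,
      (hi - lo) / diff(RESPONSE_WINDOW_MS) *
        vapply(seq_along(lags), function(i) {
          if (hi[i] <= lo[i]) 0 else window_mean(lo[i], hi[i])
        }, numeric(1)),
      0
    )
    kappa_resp <- kappa_resp + sum(lag_density * resp_fut)
    if (m < max_neighbours) {
      lag_density <- convolve_density(lag_density, d1)
      lag_start <- lag_start + iti_grid[1]
    }
  }
  list(kappa = kappa_resp - kappa_base,
       kappa_resp = kappa_resp,
       kappa_base = kappa_base)
}

overlap_coefficient <- function(n = 10.1, tmax_ms = 930,
                                iti_range_ms = c(1200, 1700),
                                max_neighbours = 4) {
  overlap_components(n, tmax_ms, iti_range_ms, max_neighbours)$kappa
}

convolve_density <- function(a, b) {
  out <- stats::convolve(a, rev(b), type = "open")
  out[out < 0] <- 0
  out / sum(out)
}

#' Convert change-score amplitudes to kernel peak amplitudes
#'
#' Ground-truth amplitudes are specified on the scale of the measured change
#' score (response-window mean minus baseline-window mean, mm^2). An isolated
#' event with kernel peak `p` produces a change of `g * p`, where `g` is the
#' window-averaged kernel gain; in a running tone sequence the responses of
#' neighbouring tones additionally leak into both windows, adding a common
#' offset `c = kappa * p_bar` (with `p_bar` the mixture-average peak over the
#' 84/8/8 tone mix and `kappa` the expected overlap per unit peak).
#' Solving `amp = g * p + kappa * p_bar` for each trial type yields the peaks
#' the simulator must inject so that measured change scores are centred on the
#' requested amplitudes.
#'
#' @param amp Named numeric vector of change-score amplitudes per trial type.
#' @param config A [session_config()].
#' @param truth A [ground_truth()] (kernel shape parameters are read from it).
#' @return Named numeric vector of kernel peak amplitudes (mm^2) with an
#'   attribute `offset` giving the common overlap offset `c`.
#' @export
calibrate_amplitudes <- function(amp, config, truth) {
  g <- kernel_window_gain(truth$kernel_n, truth$kernel_tmax_ms,
                          config$sampling_rate)
  ov <- overlap_components(truth$kernel_n, truth$kernel_tmax_ms,
                           config$iti_range_ms)
  kap <- ov$kappa
  props <- c(
    standard = 1 - config$p_oddball - config$p_deviant,
    oddball = config$p_oddball,
    deviant = config$p_deviant
  )
  amp <- amp[TRIAL_TYPES]
  a_bar <- sum(props * amp)
  offset <- kap * a_bar / (g + kap)
  peaks <- (amp - offset) / g
  attr(peaks, "offset") <- offset
  attr(peaks, "gain") <- g
  # expected leakage of the tone stream into the baseline window, used to
  # express tonic levels on the measured-baseline scale
  attr(peaks, "baseline_leakage") <- ov$kappa_base * sum(props * peaks)
  peaks
}
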