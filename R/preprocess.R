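#' Detect runs of missing pupil samples
#'
#' Maximal runs of missing pupil values (the sentinel `NA`, which on file
#' covers both empty fields and recorded areas of 0) are returned as
#' half-open mask spans labelled `blink`: for offline reprocessing, missing
#' or zeroed pupil runs stand in for the tracker's online blink flags.
#'
#' @param samples Sample tibble (`time_ms` plus a `pupil_au` or `pupil_mm2`
#'   column).
#' @return Tibble of spans: `start_ms`, `end_ms` (half-open), `reason`.
#' @export
detect_missing_runs <- function(samples) {
  pupil_col <- intersect(c("pupil_au", "pupil_mm2"), names(samples))[1]
  missing <- is.na(samples[[pupil_col]])
  runs_to_spans(missing, samples$time_ms, reason = "blink")
}

# turn a logical vector over the sample grid into half-open ms spans;
# span end = time of last flagged sample + dt
runs_to_spans <- function(flag, time_ms, reason) {
  dt <- if (length(time_ms) > 1) time_ms[2] - time_ms[1] else 2
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  tibble::tibble(
    start_ms = time_ms[starts[keep]],
    end_ms = time_ms[ends[keep]] + dt,
    reason = rep(reason, sum(keep))
  )
}

#' Extend mask spans by a safety margin
#'
#' Widens each span by `margin_ms` on both sides (the recorded pupil is
#' unstable around blink onset and offset), clips to the block's time range,
#' and merges any overlapping results into disjoint spans.
#'
#' @param spans Span tibble (`start_ms`, `end_ms`, `reason`).
#' @param margin_ms Margin on each side, default 200 ms.
#' @param block_range Length-2 numeric giving the block's half-open time
#'   range for clipping; `NULL` leaves span ends unclipped at the top and
#'   clips starts at 0.
#' @return Disjoint, sorted span tibble. Spans arising from merges keep the
#'   reason `margin` unless all members shared one reason.
#' @export
extend_margins <- function(spans, margin_ms = 200, block_range = NULL) {
  if (nrow(spans) == 0) return(spans)
  lo <- if (!is.null(block_range)) block_range[1] else 0
  hi <- if (!is.null(block_range)) block_range[2] else Inf
  out <- spans
  out$start_ms <- pmax(out$start_ms - margin_ms, lo)
  out$end_ms <- pmin(out$end_ms + margin_ms, hi)
  merge_spans(out)
}

#' Merge overlapping or touching spans into a disjoint set
#'
#' @param spans Span tibble.
#' @return Sorted, disjoint span tibble; merged spans keep a common reason
#'   or `"margin"` when reasons differ.
#' @export
merge_spans <- function(spans) {
  if (nrow(spans) <= 1) return(spans[order(spans$start_ms), ])
  spans <- spans[order(spans$start_ms, spans$end_ms), ]
  starts <- spans$start_ms
  ends <- spans$end_ms
  reasons <- spans$reason
  m_start <- starts[1]
  m_end <- ends[1]
  m_reason <- reasons[1]
  out <- list()
  for (i in seq_len(nrow(spans))[-1]) {
    if (starts[i] <= m_end) {
      m_end <- max(m_end, ends[i])
      if (!identical(reasons[i], m_reason)) m_reason <- "margin"
    } else {
      out[[length(out) + 1]] <- c(m_start, m_end, m_reason)
      m_start <- starts[i]; m_end <- ends[i]; m_reason <- reasons[i]
    }
  }
  out[[length(out) + 1]] <- c(m_start, m_end, m_reason)
  tibble::tibble(
    start_ms = as.numeric(vapply(out, `[`, "", 1)),
    end_ms = as.numeric(vapply(out, `[`, "", 2)),
    reason = vapply(out, `[`, "", 3)
  )
}

#' Mask samples where gaze leaves fixation
#'
#' The recorded pupil area depends on gaze angle, so samples whose Euclidean
#' gaze distance from the fixation cross is at or beyond the threshold
#' (default 2 degrees of visual angle; `>=` at the boundary) are flagged and
#' returned as maximal runs labelled `gaze`.
#'
#' @param samples Sample tibble with `gaze_x_deg`, `gaze_y_deg`.
#' @param threshold_deg Distance threshold in degrees.
#' @return Span tibble (reason `gaze`).
#' @export
mask_gaze_deviation <- function(samples, threshold_deg = 2.0) {
  d <- sqrt(samples$gaze_x_deg^2 + samples$gaze_y_deg^2)
  flag <- !is.na(d) & d >= threshold_deg
  runs_to_spans(flag, samples$time_ms, reason = "gaze")
}

# logical index of samples falling inside any half-open span
samples_in_spans <- function(time_ms, spans) {
  inside <- rep(FALSE, length(time_ms))
  for (i in seq_len(nrow(spans))) {
    inside <- inside | (time_ms >= spans$start_ms[i] & time_ms < spans$end_ms[i])
  }
  inside
}

#' Linearly interpolate masked samples
#'
#' Samples inside the mask spans are replaced by linear interpolation
#' between the last valid sample before and the first valid sample after
#' each gap; gaps at the block edges are filled by holding the nearest valid
#' value. Valid samples are untouched.
#'
#' @param samples Sample tibble.
#' @param spans Disjoint span tibble of samples to treat as missing.
#' @return The samples with all pupil values valid and a logical column
#'   `interpolated` marking the filled samples.
#' @export
interpolate_missing <- function(samples, spans) {
  pupil_col <- intersect(c("pupil_au", "pupil_mm2"), names(samples))[1]
  p <- samples[[pupil_col]]
  masked <- samples_in_spans(samples$time_ms, spans) | is.na(p)
  if (all(masked)) {
    abort("entire block is missing; nothing to interpolate from.")
  }
  p[masked] <- NA_real_
  p <- zoo::na.approx(p, x = samples$time_ms, na.rm = FALSE, rule = 2)
  samples[[pupil_col]] <- as.numeric(p)
  samples$interpolated <- masked
  samples
}

#' Remove the linear trend from a block, preserving its mean
#'
#' Fits an ordinary-least-squares line to pupil versus time over the whole
#' block and subtracts the slope component `b * (t - mean(t))`. The block
#' mean is preserved exactly, which keeps between-block baseline (tonic)
#' comparisons meaningful; only the slow within-block drift is removed.
#'
#' @param samples Sample tibble with valid (interpolated) pupil values.
#' @return The samples, detrended; the removed slope (units per ms) is
#'   attached as attribute `"slope"`.
#' @export
detrend_block <- function(samples) {
  pupil_col <- intersect(c("pupil_au", "pupil_mm2"), names(samples))[1]
  t <- samples$time_ms
  p <- samples[[pupil_col]]
  tc <- t - mean(t)
  b <- sum(tc * (p - mean(p))) / sum(tc^2)
  samples[[pupil_col]] <- p - b * tc
  attr(samples, "slope") <- b
  samples
}

#' Fit and apply the artificial-pupil calibration
#'
#' `fit_calibration()` fits the affine map `mm^2 = slope * au + intercept`
#' to the calibration pairs by least squares; `apply_calibration()` applies
#' it elementwise, renaming the pupil column to `pupil_mm2`.
#'
#' @param table Calibration tibble (`measured_au`, `true_area_mm2`).
#' @return `fit_calibration()`: a `calibration_curve` with `slope`,
#'   `intercept`, `residual_rmse`.
#' @export
fit_calibration <- function(table) {
  validate_calibration(table)
  fit <- lm(true_area_mm2 ~ measured_au, data = table)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope <= 0) {
    abort("calibration fit has non-positive slope; check the pairs.")
  }
  structure(
    list(
      slope = slope,
      intercept = unname(coef(fit)[1]),
      residual_rmse = sqrt(mean(fit$residuals^2))
    ),
    class = "calibration_curve"
  )
}

#' @rdname fit_calibration
#' @param samples Sample tibble with `pupil_au`.
#' @param curve A `calibration_curve`.
#' @export
apply_calibration <- function(samples, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  samples$pupil_mm2 <- curve$slope * samples$pupil_au + curve$intercept
  samples$pupil_au <- NULL
  samples
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> mm^2 = %.6g * au + %.4g (rmse %.3g mm^2)\n",
    x$slope, x$intercept, x$residual_rmse
  ))
  invisible(x)
}

#' Preprocess one block of raw samples
#'
#' Applies the full sample-level cleaning chain in order: blink-run
#' detection, 200 ms margin extension, gaze-deviation masking, union of all
#' mask spans, linear interpolation across them, mean-preserving linear
#' detrending, and affine calibration to mm^2.
#'
#' @param samples Raw sample tibble for one block.
#' @param curve A fitted `calibration_curve`.
#' @param margin_ms Blink margin (ms).
#' @param gaze_deg Gaze-deviation threshold (degrees).
#' @return List: `samples` (cleaned, with `pupil_mm2` and `interpolated`),
#'   `spans` (the disjoint mask), `qc` (fraction masked per reason).
#' @export
preprocess_block <- function(samples, curve, margin_ms = 200, gaze_deg = 2.0) {
  dt <- samples$time_ms[2] - samples$time_ms[1]
  block_range <- c(samples$time_ms[1], samples$time_ms[nrow(samples)] + dt)
  blink <- detect_missing_runs(samples)
  blink <- extend_margins(blink, margin_ms = margin_ms,
                          block_range = block_range)
  gaze <- mask_gaze_deviation(samples, threshold_deg = gaze_deg)
  spans <- merge_spans(dplyr::bind_rows(blink, gaze))
  cleaned <- interpolate_missing(samples, spans)
  cleaned <- detrend_block(cleaned)
  cleaned <- apply_calibration(cleaned, curve)
  frac <- function(sp) {
    if (nrow(sp) == 0) 0 else
      sum(pmin(sp$end_ms, block_range[2]) - pmax(sp$start_ms, block_range[1])) /
        diff(block_range)
  }
  list(
    samples = cleaned,
    spans = spans,
    qc = list(
      fraction_masked_blink = frac(blink),
      fraction_masked_gaze = frac(gaze),
      fraction_masked_total = frac(spans),
      detrend_slope_au_per_ms = attr(cleaned, "slope")
    )
  )
}

#' Preprocess every block of a session
#'
#' Fits the calibration once from the session's artificial-pupil table, then
#' runs [preprocess_block()] on each block.
#'
#' @param session A `pupil_session`.
#' @param margin_ms,gaze_deg Preprocessing parameters.
#' @return The session with cleaned `samples` (in mm^2), plus `curve`,
#'   `mask_spans` and a per-block `qc` list.
#' @export
preprocess_session <- function(session, margin_ms = 200, gaze_deg = 2.0) {
  curve <- fit_calibration(session$calibration)
  res <- lapply(session$samples, preprocess_block, curve = curve,
                margin_ms = margin_ms, gaze_deg = gaze_deg)
  session$samples <- lapply(res, `[[`, "samples")
  session$mask_spans <- lapply(res, `[[`, "spans")
  session$qc <- lapply(res, `[[`, "qc")
  session$curve <- curve
  session
}
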