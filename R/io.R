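#' Read and write pupil sample streams
#'
#' Samples are stored as TSV with the exact header
#' `time_ms gaze_x_deg gaze_y_deg pupil_au`, optionally preceded by `#`
#' comment lines recording provenance (package version, seed). An empty
#' pupil field, an explicit `NA`, or a recorded area of 0 (the tracker's
#' convention for a closed eye) all become the in-memory missing sentinel
#' `NA`. Reading validates the column set, row integrity and strict
#' monotonicity of the time grid; a violation raises an error naming the
#' offending data line. Write-then-read round-trips are lossless.
#'
#' @param path File path.
#' @return `read_samples()`: tibble with columns `time_ms`, `gaze_x_deg`,
#'   `gaze_y_deg`, `pupil_au`.
#' @name samples_io
NULL

SAMPLE_COLS <- c("time_ms", "gaze_x_deg", "gaze_y_deg", "pupil_au")
EVENT_COLS <- c("onset_ms", "trial_type", "tone_hz", "block_id", "reward",
                "response_time_ms")
CALIB_COLS <- c("measured_au", "true_area_mm2")

# number of leading '#' comment lines, to turn row indices into file lines
n_comment_lines <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  n <- 0L
  while (length(line <- readLines(con, n = 1L)) == 1L && startsWith(line, "#")) {
    n <- n + 1L
  }
  n
}

read_tsv_strict <- function(path, expected_cols, col_types) {
  hdr <- readr::read_tsv(path, comment = "#", n_max = 0,
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!identical(names(hdr), expected_cols)) {
    abort(paste0(
      "unexpected columns in ", path, ": got [",
      paste(names(hdr), collapse = ", "), "], expected [",
      paste(expected_cols, collapse = ", "), "]."
    ))
  }
  df <- readr::read_tsv(path, comment = "#", col_types = col_types,
                        na = c("", "NA"), progress = FALSE)
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(paste0(
      "malformed row in ", path, " at line ",
      probs$row[1] + n_comment_lines(path) + 1L, ": ", probs$expected[1],
      " expected."
    ))
  }
  df
}

file_header <- function(seed = NULL) {
  v <- as.character(utils::packageVersion("oddpupil"))
  h <- paste0("# oddpupil v", v)
  if (!is.null(seed)) h <- c(h, paste0("# seed: ", seed))
  h
}

#' @rdname samples_io
#' @export
read_samples <- function(path) {
  df <- read_tsv_strict(path, SAMPLE_COLS, readr::cols(
    time_ms = readr::col_double(),
    gaze_x_deg = readr::col_double(),
    gaze_y_deg = readr::col_double(),
    pupil_au = readr::col_double()
  ))
  bad <- which(diff(df$time_ms) <= 0)
  if (length(bad) > 0) {
    abort(paste0(
      "non-monotone time in ", path, " at line ",
      bad[1] + 1L + n_comment_lines(path) + 1L, "."
    ))
  }
  df$pupil_au[!is.na(df$pupil_au) & df$pupil_au == 0] <- NA_real_
  df
}

#' @rdname samples_io
#' @param samples Sample tibble as returned by [read_samples()].
#' @param seed Optional seed recorded in the comment header.
#' @export
write_samples <- function(samples, path, seed = NULL) {
  stopifnot(all(SAMPLE_COLS %in% names(samples)))
  writeLines(file_header(seed), path)
  readr::write_tsv(samples[SAMPLE_COLS], path, append = TRUE,
                   col_names = TRUE, na = "")
  invisible(path)
}

#' Read and write event logs
#'
#' Events are TSV with header
#' `onset_ms trial_type tone_hz block_id reward response_time_ms`; the
#' literal `NA` in the response column means no manual response was made.
#' `trial_type` must come from `standard`/`oddball`/`deviant` and `reward`
#' from `low`/`high`/`none`; anything else is rejected.
#'
#' @param path File path.
#' @return `read_events()`: event tibble.
#' @name events_io
NULL

#' @rdname events_io
#' @export
read_events <- function(path) {
  df <- read_tsv_strict(path, EVENT_COLS, readr::cols(
    onset_ms = readr::col_double(),
    trial_type = readr::col_character(),
    tone_hz = readr::col_double(),
    block_id = readr::col_integer(),
    reward = readr::col_character(),
    response_time_ms = readr::col_double()
  ))
  bad_type <- setdiff(unique(df$trial_type), TRIAL_TYPES)
  if (length(bad_type) > 0) {
    abort(paste0(
      "unknown trial_type '", bad_type[1], "' in ", path,
      " (expected standard/oddball/deviant)."
    ))
  }
  bad_rw <- setdiff(unique(df$reward), REWARD_LEVELS)
  if (length(bad_rw) > 0) {
    abort(paste0("unknown reward label '", bad_rw[1], "' in ", path, "."))
  }
  # times are block-relative, so sortedness is required within each block
  unsorted <- tapply(df$onset_ms, df$block_id, is.unsorted)
  if (any(unsorted)) {
    abort(paste0("events in ", path, " are not sorted by onset within block ",
                 names(unsorted)[unsorted][1], "."))
  }
  df
}

#' @rdname events_io
#' @param events Event tibble.
#' @param seed Optional seed recorded in the comment header.
#' @export
write_events <- function(events, path, seed = NULL) {
  stopifnot(all(EVENT_COLS %in% names(events)))
  writeLines(file_header(seed), path)
  readr::write_tsv(events[EVENT_COLS], path, append = TRUE, col_names = TRUE,
                   na = "NA")
  invisible(path)
}

#' Read and write artificial-pupil calibration tables
#'
#' Calibration pairs map the tracker's arbitrary units to true areas (mm^2)
#' of laser-printed artificial pupils. At least two distinct au readings are
#' required (an affine fit is underdetermined otherwise) and all areas must
#' be positive. Duplicate au readings with conflicting areas are retained;
#' the least-squares fit handles them.
#'
#' @param path File path.
#' @return `read_calibration()`: tibble with `measured_au`, `true_area_mm2`.
#' @name calibration_io
NULL

#' @rdname calibration_io
#' @export
read_calibration <- function(path) {
  df <- read_tsv_strict(path, CALIB_COLS, readr::cols(
    measured_au = readr::col_double(),
    true_area_mm2 = readr::col_double()
  ))
  validate_calibration(df, path)
}

validate_calibration <- function(df, label = "calibration table") {
  if (length(unique(df$measured_au)) < 2) {
    abort(paste0(label, " needs >= 2 distinct au values for an affine fit."))
  }
  if (any(df$true_area_mm2 <= 0)) {
    abort(paste0(label, " contains non-positive areas."))
  }
  df
}

#' @rdname calibration_io
#' @param calibration Calibration tibble.
#' @export
write_calibration <- function(calibration, path) {
  stopifnot(all(CALIB_COLS %in% names(calibration)))
  writeLines(file_header(), path)
  readr::write_tsv(calibration[CALIB_COLS], path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

#' Write or read a complete simulated session directory
#'
#' Lays out one directory per participant: `block<k>_samples.tsv` per block,
#' a combined `events.tsv`, `calibration.tsv`, `config.yaml` (including the
#' per-block reward and response-mode labels) and `truth.json` (the full
#' ground truth plus realised participant draws), so every simulation is
#' fully reconstructable and recovery tests can compare estimates to truth.
#'
#' @param session A `pupil_session` from [simulate_session()].
#' @param dir Output directory (created if needed).
#' @return `write_session()`: the directory, invisibly. `read_session()`: a
#'   `pupil_session` (without ground truth if `truth.json` is absent).
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "pupil_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- session$realized$seed
  for (b in seq_along(session$samples)) {
    write_samples(session$samples[[b]],
                  file.path(dir, sprintf("block%d_samples.tsv", b)),
                  seed = seed)
  }
  write_events(session$events, file.path(dir, "events.tsv"), seed = seed)
  write_calibration(session$calibration, file.path(dir, "calibration.tsv"))
  cfg <- unclass(session$config)
  cfg$participant_id <- session$participant_id
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  truth <- unclass(session$truth)
  truth$realized <- session$realized[c("tonic_dev", "amp_dev", "seed")]
  jsonlite::write_json(named_to_list(truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

# JSON objects keep names; named atomic vectors would serialise as bare
# arrays, so convert them (recursively) to lists first
named_to_list <- function(x) {
  if (is.atomic(x) && !is.null(names(x))) {
    as.list(x)
  } else if (is.list(x)) {
    lapply(x, named_to_list)
  } else {
    x
  }
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  cfg_raw <- yaml::read_yaml(file.path(dir, "config.yaml"))
  participant_id <- cfg_raw$participant_id %||% basename(dir)
  cfg_raw$participant_id <- NULL
  config <- do.call(session_config, cfg_raw[setdiff(
    names(cfg_raw),
    setdiff(names(cfg_raw), names(formals(session_config)))
  )])
  sample_files <- sort(list.files(dir, pattern = "^block\\d+_samples\\.tsv$",
                                  full.names = TRUE))
  block_no <- as.integer(sub("^block(\\d+)_samples\\.tsv$", "\\1",
                             basename(sample_files)))
  samples <- lapply(sample_files[order(block_no)], read_samples)
  events <- read_events(file.path(dir, "events.tsv"))
  calibration <- read_calibration(file.path(dir, "calibration.tsv"))
  truth <- NULL
  truth_path <- file.path(dir, "truth.json")
  realized <- NULL
  if (file.exists(truth_path)) {
    tj <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    realized <- tj$realized
    tj$realized <- NULL
    tj$amp <- lapply(tj$amp, unlist)
    truth_args <- tj[intersect(names(tj), names(formals(ground_truth)))]
    flatten <- setdiff(names(truth_args), "amp")
    truth_args[flatten] <- lapply(truth_args[flatten], function(x) {
      if (is.list(x) && !is.null(names(x)) && all(vapply(x, is.numeric, TRUE))) {
        unlist(x)
      } else {
        x
      }
    })
    truth <- do.call(ground_truth, truth_args)
  }
  structure(
    list(
      participant_id = participant_id,
      samples = samples,
      events = events,
      calibration = calibration,
      config = config,
      truth = truth,
      realized = realized
    ),
    class = "pupil_session"
  )
}
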