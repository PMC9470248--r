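#' Run the full analysis chain on simulated sessions
#'
#' Convenience driver for in-memory studies: preprocess every session,
#' compute per-trial measures, apply the error exclusions, and run the
#' experiment's statistical analysis.
#'
#' @param sessions List of `pupil_session` objects (see [simulate_study()]),
#'   or a single session.
#' @param experiment Analysis design (`"exp1"`, `"exp2"`, `"exp3"`).
#' @param margin_ms,gaze_deg Preprocessing parameters.
#' @param random Random-effect structure for [fit_lmm()].
#' @return An `oddball_report` with an added `exclusions` element and the
#'   pooled `measures` table attached as attribute `"measures"`.
#' @export
analyze_sessions <- function(sessions, experiment = "exp1",
                             margin_ms = 200, gaze_deg = 2.0,
                             random = "auto") {
  if (inherits(sessions, "pupil_session")) sessions <- list(sessions)
  measures <- dplyr::bind_rows(lapply(sessions, function(s) {
    compute_measures(preprocess_session(s, margin_ms = margin_ms,
                                        gaze_deg = gaze_deg))
  }))
  excl <- apply_exclusions(measures)
  report <- analyze_experiment(excl$measures, experiment, random = random)
  report$exclusions <- excl$report
  attr(report, "measures") <- excl$measures
  report
}

#' Run the pipeline from a config file or config list
#'
#' Orchestrates simulate -> preprocess -> epochs -> analyze with a single
#' YAML config, writing a report bundle (JSON report, measures TSV, run
#' manifest) to the output directory. Deterministic given config plus seed.
#'
#' The config supports:
#' \describe{
#'   \item{experiment}{`exp1`/`exp2`/`exp3`.}
#'   \item{n_participants}{Number of simulated participants (simulate mode).}
#'   \item{data_dir}{Directory of existing session subdirectories to analyse
#'     instead of simulating.}
#'   \item{seed}{Master seed.}
#'   \item{sampling_rate, trials_per_block}{Design scale-down overrides.}
#'   \item{margin_ms, gaze_deg}{Preprocessing parameters.}
#'   \item{random}{Random-effect structure (`auto` by default).}
#'   \item{keep_sessions}{Write the simulated sessions under
#'     `out/sessions/`.}
#' }
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @param out Output directory for the report bundle (`NULL`: nothing
#'   written).
#' @return The `oddball_report`, invisibly when `out` is given.
#' @export
run_pipeline <- function(config, out = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  experiment <- config$experiment %||% "exp1"
  seed <- as.integer(config$seed %||% 1L)
  margin_ms <- config$margin_ms %||% 200
  gaze_deg <- config$gaze_deg %||% 2.0
  random <- config$random %||% "auto"

  if (!is.null(config$data_dir)) {
    if (!dir.exists(config$data_dir)) {
      abort(paste0("data_dir not found: ", config$data_dir))
    }
    dirs <- list.dirs(config$data_dir, recursive = FALSE)
    dirs <- dirs[file.exists(file.path(dirs, "events.tsv"))]
    if (length(dirs) == 0) abort("data_dir contains no session directories.")
    sessions <- lapply(dirs, read_session)
    message(sprintf("read %d session(s) from %s", length(sessions),
                    config$data_dir))
  } else {
    n_participants <- config$n_participants %||% 24L
    sessions <- simulate_study(
      experiment, n_participants = n_participants, seed = seed,
      sampling_rate = config$sampling_rate %||% 500,
      trials_per_block = config$trials_per_block
    )
    message(sprintf("simulated %d session(s) for %s (seed %d)",
                    length(sessions), experiment, seed))
    if (isTRUE(config$keep_sessions) && !is.null(out)) {
      for (s in sessions) {
        write_session(s, file.path(out, "sessions", s$participant_id))
      }
    }
  }

  report <- analyze_sessions(sessions, experiment = experiment,
                             margin_ms = margin_ms, gaze_deg = gaze_deg,
                             random = random)
  message(sprintf(
    "analyzed %d trials from %d participant(s); %d error trial(s) removed, %d participant(s) excluded",
    nrow(attr(report, "measures")),
    length(unique(attr(report, "measures")$participant)),
    report$exclusions$n_error_trials_removed,
    report$exclusions$n_participants_excluded
  ))

  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report_to_list(report),
                         file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    readr::write_tsv(attr(report, "measures"),
                     file.path(out, "measures.tsv"))
    manifest <- list(
      package_version = as.character(utils::packageVersion("oddpupil")),
      experiment = experiment, seed = seed,
      margin_ms = margin_ms, gaze_deg = gaze_deg, random = random,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(report))
  }
  report
}

# strip model objects so the report serialises cleanly to JSON
report_to_list <- function(report) {
  out <- list(
    experiment = report$experiment,
    model = report$model,
    emm = lapply(report$emm, as.data.frame),
    contrasts = as.data.frame(report$contrasts),
    exclusions = list(
      n_participants_excluded = report$exclusions$n_participants_excluded,
      n_error_trials_removed = report$exclusions$n_error_trials_removed,
      participants = as.data.frame(report$exclusions$participants)
    )
  )
  if (!is.null(report$tonic)) {
    out$tonic <- list(
      emm = as.data.frame(report$tonic$emm),
      contrast = as.data.frame(report$tonic$contrast)
    )
  }
  if (!is.null(report$rt)) {
    out$rt <- report$rt[c("F", "df1", "df2", "p", "partial_eta2")]
    out$rt$cell_means <- as.data.frame(report$rt$cell_means)
  }
  out
}

#' Plot grand-average pupil responses by condition
#'
#' Time-course visualisation of the mean epoch per trial type (and optional
#' grouping condition), baseline-corrected per trial. Requires ggplot2.
#'
#' @param sessions Preprocessed sessions (list or single `pupil_session`).
#' @param group Optional extra grouping column of the event table
#'   (`"reward"`).
#' @return A ggplot object.
#' @export
plot_mean_response <- function(sessions, group = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("plot_mean_response requires ggplot2.")
  }
  if (inherits(sessions, "pupil_session")) sessions <- list(sessions)
  rate <- sessions[[1]]$config$sampling_rate
  dt <- 1000 / rate
  t_rel <- seq(EPOCH_WINDOW_MS[1], EPOCH_WINDOW_MS[2] - dt, by = dt)
  rows <- list()
  for (s in sessions) {
    for (b in seq_along(s$samples)) {
      ev_b <- s$events[s$events$block_id == b, , drop = FALSE]
      if (nrow(ev_b) == 0) next
      ex <- suppressWarnings(extract_epochs(s$samples[[b]], ev_b, rate))
      base <- colMeans(ex$epochs[seq_len(as.integer(-EPOCH_WINDOW_MS[1] / dt)),
                                 , drop = FALSE])
      centred <- sweep(ex$epochs, 2, base)
      g <- if (is.null(group)) "all" else ex$events[[group]]
      for (lev in unique(ex$events$trial_type)) {
        for (gl in unique(g)) {
          sel <- ex$events$trial_type == lev & g == gl
          if (!any(sel)) next
          rows[[length(rows) + 1]] <- tibble::tibble(
            time_ms = t_rel,
            pupil = rowMeans(centred[, sel, drop = FALSE]),
            trial_type = lev, group = gl
          )
        }
      }
    }
  }
  df <- dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$time_ms, .data$trial_type, .data$group) |>
    dplyr::summarise(pupil = mean(.data$pupil), .groups = "drop")
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$pupil,
                                        colour = .data$trial_type)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time from tone onset (ms)",
                  y = "pupil change from baseline (mm^2)") +
    ggplot2::theme_minimal()
  if (!is.null(group)) {
    p <- p + ggplot2::facet_wrap(~group)
  }
  p
}
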