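# Delimited-text and JSON persistence. Matrices travel as wide CSV (one row
# per cell, columns f_0, f_1, ...); schedules, configs and summaries as JSON.

#' Write and read trace matrices as delimited text
#'
#' Wide CSV layout: one row per cell with a `cell_id` column followed by
#' `f_0, f_1, ...` frame columns.
#'
#' @param traces Long tibble `cell_id`, `time_s`, plus a value column.
#' @param path File path.
#' @param value Name of the value column to write (default `"fluor"`).
#' @return `write_traces()` returns `path` invisibly; `read_traces()`
#'   returns a long trace tibble with `frame_rate_hz`/`t0_s` attributes.
#' @export
write_traces <- function(traces, path, value = "fluor") {
  stopifnot(value %in% names(traces))
  wide <- traces |>
    select("cell_id", "time_s", all_of(value)) |>
    mutate(frame = paste0("f_", as.integer(round(
      (.data$time_s - min(.data$time_s)) * trace_frame_rate(traces)))))
  wide <- tidyr::pivot_wider(wide, id_cols = "cell_id",
                             names_from = "frame", values_from = all_of(value))
  readr::write_csv(wide, path)
  invisible(path)
}

#' @rdname write_traces
#' @param frame_rate_hz Frames per second of the stored matrix.
#' @param t0_s Time of the first frame (s).
#' @param value_name Column name for the values in the long result.
#' @export
read_traces <- function(path, frame_rate_hz = 8, t0_s = 0, value_name = "fluor") {
  wide <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(names(wide)[1] == "cell_id")
  n_frames <- ncol(wide) - 1
  ids <- factor(wide$cell_id, levels = wide$cell_id)
  out <- tibble(
    cell_id = rep(ids, each = n_frames),
    time_s = rep(frame_times(n_frames, frame_rate_hz, t0_s), nrow(wide)),
    value = as.vector(t(as.matrix(wide[, -1]))))
  names(out)[3] <- value_name
  set_trace_attrs(out, frame_rate_hz = frame_rate_hz, t0_s = t0_s)
}

#' Write and read event schedules as JSON
#'
#' @param schedule An [event_schedule()].
#' @param path File path.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "event_schedule"))
  jsonlite::write_json(unclass(schedule), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  event_schedule(stimulus_onset_s = x$stimulus_onset_s,
                 bout_onsets_s = x$bout_onsets_s %||% numeric(0),
                 session_duration_s = x$session_duration_s,
                 condition = x$condition %||% "unspecified")
}

#' Write and read event trains as delimited text
#'
#' Two-column CSV `cell_id, event_time_s`.
#'
#' @param events A [detect_transients()] result or compatible tibble.
#' @param path File path.
#' @export
write_events <- function(events, path) {
  readr::write_csv(tibble(cell_id = as.character(events$cell_id),
                          event_time_s = events$event_time_s), path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  mutate(x, cell_id = factor(.data$cell_id, levels = unique(.data$cell_id)))
}

#' Write and read scenario / analysis configurations as JSON
#'
#' @param config A [scenario_config()] or [analysis_config()].
#' @param path File path.
#' @export
write_config <- function(config, path) {
  kind <- class(config)[1]
  x <- unclass(config)
  if (!is.null(x$fractions)) x$fractions <- as.list(x$fractions)
  jsonlite::write_json(c(list(kind = kind), x), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  kind <- x$kind %||% "scenario_config"
  x$kind <- NULL
  if (kind == "analysis_config") {
    do.call(analysis_config, x)
  } else {
    if (!is.null(x$fractions)) x$fractions <- unlist(x$fractions)
    if (!is.null(x$bout_onsets_s) && length(x$bout_onsets_s) == 0) {
      x$bout_onsets_s <- NULL
    }
    do.call(scenario_config, x)
  }
}

#' Persist a pipeline run
#'
#' Writes every stage artifact of a [run_pipeline()] result to `dir`:
#' \eqn{\Delta F/F_0} and residual matrices plus a JSON sidecar of per-cell
#' baseline statistics, the event train CSV, per-cell labels and bout flags
#' as CSV, and a single `report.json` holding the configuration (and its
#' hash), classification summary, transient counts, bout summary and paired
#' test. Rerunning on identical inputs reproduces every file byte for byte.
#'
#' @param analysis A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return The report file path, invisibly.
#' @export
write_report <- function(analysis, dir) {
  stopifnot(inherits(analysis, "ca_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)

  write_traces(analysis$dff, p("dff.csv"), value = "dff")
  write_traces(analysis$detrended, p("residual.csv"), value = "resid")
  base <- baseline_stats(analysis$dff)
  jsonlite::write_json(
    list(config_hash = analysis$config_hash,
         cells = lapply(seq_len(nrow(base)), function(i) list(
           cell_id = as.character(base$cell_id[i]), f0 = base$f0[i],
           baseline_mean = base$baseline_mean[i], sigma = base$sigma[i]))),
    p("baseline.json"), auto_unbox = TRUE, digits = NA)
  write_events(analysis$events, p("events.csv"))
  readr::write_csv(
    mutate(as_tibble(analysis$classes), cell_id = as.character(.data$cell_id),
           label = as.character(.data$label)),
    p("labels.csv"))
  if (!is.null(analysis$bouts)) {
    readr::write_csv(
      mutate(as_tibble(analysis$bouts), cell_id = as.character(.data$cell_id)),
      p("bout_flags.csv"))
  }

  cells_attr <- attr(analysis$events, "cells")
  report <- list(
    config_hash = analysis$config_hash,
    config = unclass(analysis$config),
    condition = analysis$schedule$condition,
    n_cells = nrow(analysis$classes),
    classification = list(
      counts = as.list(stats::setNames(analysis$class_summary$n,
                                       as.character(analysis$class_summary$label))),
      pct = as.list(stats::setNames(analysis$class_summary$pct,
                                    as.character(analysis$class_summary$label)))),
    transients = list(
      total = nrow(analysis$events),
      per_cell = lapply(seq_len(nrow(cells_attr)), function(i) list(
        cell_id = as.character(cells_attr$cell_id[i]),
        mad = cells_attr$mad[i], threshold = cells_attr$threshold[i],
        n_events = cells_attr$n_events[i]))),
    bout_correlation = if (!is.null(analysis$bouts)) {
      s <- attr(analysis$bouts, "summary")
      list(n_cells = s$n_cells, n_correlated = s$n_correlated,
           pct_correlated = s$pct_correlated,
           window = attr(analysis$bouts, "window"),
           tol_s = attr(analysis$bouts, "tol_s"))
    },
    paired_test = unclass(analysis$paired_test),
    heatmap_order = analysis$heatmap$order,
    notes = analysis$notes)
  jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(p("report.json"))
}
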