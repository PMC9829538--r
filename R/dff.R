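#' Convert raw fluorescence to \eqn{\Delta F/F_0}
#'
#' For each cell, the baseline fluorescence \eqn{F_0} is the mean raw
#' fluorescence over the pre-stimulus baseline window (2 min before food
#' presentation by default), and
#' \eqn{\Delta F/F_0(t) = (F(t) - F_0) / F_0}. The per-cell baseline
#' statistics — \eqn{F_0}, the baseline mean of \eqn{\Delta F/F_0} (zero by
#' construction when the windows coincide) and its sample standard deviation
#' \eqn{\sigma} — are attached as the `"baseline"` attribute (see
#' [baseline_stats()]) and are the single source of \eqn{\sigma} for the
#' up/down classifier.
#'
#' @param traces Long tibble `cell_id`, `time_s`, `fluor` (e.g.
#'   `simulate_session()$traces` or [read_traces()] output).
#' @param baseline_window Half-open interval `c(start, stop)` in seconds;
#'   must lie within the session and contain at least 2 frames.
#' @return Tibble `cell_id`, `time_s`, `dff` of class `dff_traces`, with
#'   attributes `baseline` (per-cell tibble `cell_id`, `f0`,
#'   `baseline_mean`, `sigma`), `baseline_window` and `frame_rate_hz`.
#' @examples
#' s <- simulate_session(scenario_config(n_cells = 3, seed = 1))
#' dff <- compute_dff(s$traces, c(0, 120))
#' baseline_stats(dff)
#' @export
compute_dff <- function(traces, baseline_window = c(0, 120)) {
  stopifnot(all(c("cell_id", "time_s", "fluor") %in% names(traces)))
  fs <- trace_frame_rate(traces)
  check_window(baseline_window, trace_session_range(traces), "baseline_window")
  sel <- in_window(traces$time_s, baseline_window)
  if (sum(sel) < 2 * nlevels(factor(traces$cell_id))) {
    abort("`baseline_window` must contain at least 2 frames per cell.",
          class = "bingetrace_window_error")
  }

  base <- traces |>
    filter(sel) |>
    group_by(.data$cell_id) |>
    summarise(f0 = mean(.data$fluor), .groups = "drop")
  if (any(base$f0 <= 0)) {
    bad <- paste(base$cell_id[base$f0 <= 0], collapse = ", ")
    abort(paste0("degenerate baseline: non-positive F0 for cell(s) ", bad,
                 "; these traces are unusable for deltaF/F0."),
          class = "bingetrace_degenerate_baseline_error")
  }

  out <- traces |>
    left_join(base, by = "cell_id") |>
    mutate(dff = (.data$fluor - .data$f0) / .data$f0) |>
    select("cell_id", "time_s", "dff")

  baseline <- out |>
    filter(in_window(.data$time_s, baseline_window)) |>
    group_by(.data$cell_id) |>
    summarise(baseline_mean = mean(.data$dff),
              sigma = sd(.data$dff), .groups = "drop") |>
    left_join(base, by = "cell_id") |>
    select("cell_id", "f0", "baseline_mean", "sigma")

  out <- set_trace_attrs(out, traces,
                         baseline = baseline,
                         baseline_window = baseline_window,
                         frame_rate_hz = fs)
  class(out) <- c("dff_traces", setdiff(class(out), "dff_traces"))
  out
}

#' Per-cell baseline statistics of a \eqn{\Delta F/F_0} trace set
#'
#' @param dff A [compute_dff()] result.
#' @return Tibble `cell_id`, `f0`, `baseline_mean`, `sigma`.
#' @export
baseline_stats <- function(dff) {
  b <- attr(dff, "baseline")
  if (is.null(b)) abort("`dff` carries no baseline attribute; run compute_dff() first.",
                        class = "bingetrace_parameter_error")
  b
}

#' Remove slow drift with a sliding median filter
#'
#' Estimates each cell's slow drift as the sliding median of its
#' \eqn{\Delta F/F_0} trace in a window of `filter_width_s` seconds (10 s by
#' default — 81 samples at 8 frames/s) and subtracts it. The window length
#' in samples is `round(filter_width_s * frame_rate_hz)`, forced odd by
#' adding one if even; edges are handled by reflection padding, so the
#' residual has the same length as the input.
#'
#' @param dff A [compute_dff()] result.
#' @param filter_width_s Filter width in seconds; must span at least 3
#'   samples.
#' @return The input tibble with an added `resid` column, class
#'   `detrended_traces`; attributes of `dff` are carried over plus
#'   `filter_width_s` and `filter_width_frames`.
#' @export
median_detrend <- function(dff, filter_width_s = 10) {
  stopifnot(all(c("cell_id", "time_s", "dff") %in% names(dff)))
  check_positive(filter_width_s, "filter_width_s")
  fs <- trace_frame_rate(dff)
  w <- round(filter_width_s * fs)
  if (w %% 2 == 0) w <- w + 1
  if (w < 3) {
    abort("`filter_width_s` must span at least 3 samples at this frame rate.",
          class = "bingetrace_parameter_error")
  }

  out <- dff |>
    group_by(.data$cell_id) |>
    mutate(resid = .data$dff - sliding_median(.data$dff, w)) |>
    ungroup()

  out <- set_trace_attrs(out, dff,
                         filter_width_s = filter_width_s,
                         filter_width_frames = w)
  class(out) <- c("detrended_traces", setdiff(class(out), "detrended_traces"))
  out
}

# Sliding median with reflection padding (mirror about the edge sample,
# excluding it), full window everywhere.
sliding_median <- function(x, w) {
  n <- length(x)
  h <- (w - 1) / 2
  if (n < h + 1) {
    abort("trace shorter than half the median filter window.",
          class = "bingetrace_parameter_error")
  }
  xp <- c(x[(h + 1):2], x, x[(n - 1):(n - h)])
  as.numeric(runmed(xp, w, endrule = "keep"))[(h + 1):(h + n)]
}

#' Gaussian smoothing for display
#'
#' Convolves each cell's \eqn{\Delta F/F_0} trace with a unit-area Gaussian
#' kernel (reflection padding). Intended only for visual presentation (heat
#' maps, example traces); transient detection and response classification
#' always run on unsmoothed data.
#'
#' @param dff A [compute_dff()] result (or any trace tibble with a `dff`
#'   column).
#' @param sigma_s Gaussian standard deviation in seconds.
#' @return The input tibble with an added `smoothed` column.
#' @export
gaussian_smooth <- function(dff, sigma_s = 0.5) {
  stopifnot(all(c("cell_id", "time_s", "dff") %in% names(dff)))
  check_positive(sigma_s, "sigma_s")
  fs <- trace_frame_rate(dff)
  sigma_f <- sigma_s * fs
  r <- max(1L, ceiling(4 * sigma_f))
  kern <- dnorm(-r:r, sd = sigma_f)
  kern <- kern / sum(kern)

  smooth_one <- function(x) {
    n <- length(x)
    if (n < r + 1) {
      abort("trace shorter than the smoothing kernel radius.",
            class = "bingetrace_parameter_error")
    }
    xp <- c(x[(r + 1):2], x, x[(n - 1):(n - r)])
    as.numeric(stats::filter(xp, kern, sides = 2))[(r + 1):(r + n)]
  }

  out <- dff |>
    group_by(.data$cell_id) |>
    mutate(smoothed = smooth_one(.data$dff)) |>
    ungroup()
  set_trace_attrs(out, dff)
}
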