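# Shared internal helpers: window arithmetic, trace-attribute bookkeeping,
# largest-remainder apportionment.

# Frame k (0-based) covers [k/fs, (k+1)/fs); windows are half-open [start, stop)
# in seconds from session start.
frame_times <- function(n_frames, frame_rate_hz, t0_s = 0) {
  t0_s + (seq_len(n_frames) - 1) / frame_rate_hz
}

in_window <- function(time_s, window) {
  time_s >= window[1] & time_s < window[2]
}

check_window <- function(window, session_range, arg = "window") {
  if (!is.numeric(window) || length(window) != 2 || any(!is.finite(window)) ||
      window[2] <= window[1]) {
    abort(sprintf("`%s` must be a finite numeric interval c(start, stop) with stop > start.", arg),
          class = "bingetrace_window_error")
  }
  if (!missing(session_range) &&
      (window[1] < session_range[1] - 1e-9 || window[2] > session_range[2] + 1e-9)) {
    abort(sprintf("`%s` [%g, %g) lies outside the session [%g, %g).",
                  arg, window[1], window[2], session_range[1], session_range[2]),
          class = "bingetrace_window_error")
  }
  invisible(window)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number.", name),
          class = "bingetrace_parameter_error")
  }
  invisible(x)
}

trace_frame_rate <- function(x) {
  fs <- attr(x, "frame_rate_hz")
  if (is.null(fs)) {
    dt <- x |>
      dplyr::group_by(.data$cell_id) |>
      dplyr::summarise(dt = median(diff(.data$time_s)), .groups = "drop")
    fs <- 1 / median(dt$dt)
  }
  fs
}

trace_session_range <- function(x) {
  fs <- trace_frame_rate(x)
  c(min(x$time_s), max(x$time_s) + 1 / fs)
}

# Carry/refresh standard trace attributes after dplyr operations.
set_trace_attrs <- function(x, template = NULL, ...) {
  dots <- list(...)
  keep <- c("frame_rate_hz", "t0_s", "baseline", "baseline_window",
            "filter_width_s", "filter_width_frames", "cells",
            "threshold_k", "min_interval_s")
  if (!is.null(template)) {
    for (a in keep) {
      if (is.null(attr(x, a)) && !is.null(attr(template, a))) {
        attr(x, a) <- attr(template, a)
      }
    }
  }
  for (a in names(dots)) attr(x, a) <- dots[[a]]
  x
}

# Deterministic integer apportionment of `n` items to fractions summing to 1:
# floor the quotas, then hand remaining units to the largest remainders
# (ties broken by position). Guarantees sum(counts) == n.
largest_remainder <- function(fractions, n) {
  quota <- fractions * n
  base <- floor(quota)
  k <- n - sum(base)
  if (k > 0) {
    idx <- order(quota - base, decreasing = TRUE)[seq_len(k)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

# Round proportions to one decimal percent so the rounded values sum to 100.0.
percent_round <- function(prop, digits = 1) {
  scale <- 10^digits
  largest_remainder(prop, as.integer(round(100 * scale))) / scale
}

cell_levels <- function(cell_id) {
  if (is.factor(cell_id)) levels(cell_id) else unique(as.character(cell_id))
}

make_cell_ids <- function(n) {
  width <- max(3L, nchar(as.character(n)))
  factor(sprintf(paste0("cell_%0", width, "d"), seq_len(n)),
         levels = sprintf(paste0("cell_%0", width, "d"), seq_len(n)))
}

split_by_cell <- function(x, col) {
  split(x[[col]], factor(x$cell_id, levels = cell_levels(x$cell_id)))
}
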