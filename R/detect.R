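#' Median absolute deviation of a series
#'
#' Raw (unscaled) MAD: `median(|x - median(x)|)`. No normal-consistency
#' factor is applied, so for Gaussian data MAD \eqn{\approx 0.6745\sigma}
#' and a 6-MAD threshold corresponds to about \eqn{4\sigma} — the
#' equivalence the detection threshold relies on.
#'
#' @param series Non-empty numeric vector of finite values.
#' @return The raw MAD (same units as `series`).
#' @examples
#' compute_mad(c(1, 2, 3, 4, 100)) # 1
#' @export
compute_mad <- function(series) {
  if (length(series) < 1) {
    abort("`series` must be non-empty.", class = "bingetrace_parameter_error")
  }
  if (any(!is.finite(series))) {
    abort("`series` must be finite.", class = "bingetrace_parameter_error")
  }
  mad(series, constant = 1)
}

#' Detect calcium transients by MAD thresholding
#'
#' For each cell the raw MAD of the entire detrended residual series is
#' computed, and transients are extracted by scanning left to right: an
#' event is registered at the first sample whose residual strictly exceeds
#' `threshold_k * MAD` (6 MAD by default, about \eqn{4\sigma} for Gaussian
#' noise) and whose time follows the previously registered event by at least
#' `min_interval_s` (2 s by default; the first event has no predecessor
#' constraint). Suprathreshold samples inside the refractory interval are
#' absorbed into the previous event. The event time is the onset
#' (threshold-crossing) sample time. A cell whose residual MAD is zero
#' (flat trace) yields no events, with a warning.
#'
#' @param detrended A [median_detrend()] result.
#' @param threshold_k Threshold in MAD multiples (> 0).
#' @param min_interval_s Refractory interval in seconds (>= 0), measured
#'   onset-to-onset.
#' @return Tibble `cell_id`, `event_time_s` of class `transient_train`
#'   (sorted within cell; cells with no events contribute no rows), with
#'   attributes `cells` (per-cell tibble `cell_id`, `mad`, `threshold`,
#'   `n_events`), `threshold_k`, `min_interval_s` and `frame_rate_hz`.
#' @export
detect_transients <- function(detrended, threshold_k = 6, min_interval_s = 2) {
  stopifnot(all(c("cell_id", "time_s", "resid") %in% names(detrended)))
  check_positive(threshold_k, "threshold_k")
  if (!is.numeric(min_interval_s) || length(min_interval_s) != 1 ||
      !is.finite(min_interval_s) || min_interval_s < 0) {
    abort("`min_interval_s` must be a single non-negative number.",
          class = "bingetrace_parameter_error")
  }
  fs <- trace_frame_rate(detrended)

  res_by_cell <- split_by_cell(detrended, "resid")
  t_by_cell <- split_by_cell(detrended, "time_s")
  ids <- names(res_by_cell)

  flat <- character(0)
  per_cell <- vector("list", length(ids))
  ev <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    x <- res_by_cell[[j]]
    tt <- t_by_cell[[j]]
    m <- compute_mad(x)
    if (m == 0) {
      flat <- c(flat, ids[j])
      times <- numeric(0)
    } else {
      times <- scan_events(x, tt, threshold_k * m, min_interval_s)
    }
    per_cell[[j]] <- tibble(cell_id = ids[j], mad = m,
                            threshold = threshold_k * m,
                            n_events = length(times))
    ev[[j]] <- tibble(cell_id = rep(ids[j], length(times)), event_time_s = times)
  }
  if (length(flat)) {
    warn(paste0("zero MAD (flat residual) for cell(s) ",
                paste(flat, collapse = ", "), "; reporting no events."))
  }

  lev <- cell_levels(detrended$cell_id)
  out <- bind_rows(ev) |>
    mutate(cell_id = factor(.data$cell_id, levels = lev))
  cells <- bind_rows(per_cell) |>
    mutate(cell_id = factor(.data$cell_id, levels = lev))
  out <- set_trace_attrs(out, cells = cells,
                         threshold_k = threshold_k,
                         min_interval_s = min_interval_s,
                         frame_rate_hz = fs)
  class(out) <- c("transient_train", setdiff(class(out), "transient_train"))
  out
}

# Greedy left-to-right threshold scan over precomputed suprathreshold
# indices; equivalent to the sample-by-sample rule but O(#crossings).
scan_events <- function(x, times, threshold, min_interval_s) {
  idx <- which(x > threshold)
  if (!length(idx)) return(numeric(0))
  out <- numeric(length(idx))
  k <- 0L
  last <- -Inf
  for (i in idx) {
    if (times[i] - last >= min_interval_s - 1e-9) {
      k <- k + 1L
      out[k] <- times[i]
      last <- times[i]
    }
  }
  out[seq_len(k)]
}

#' Score detected transients against simulator ground truth
#'
#' Greedy one-to-one matching in time order: each detected event (ascending)
#' is matched to the earliest unmatched true event within
#' `±match_tol_s`. Sensitivity = matched / true, precision =
#' matched / detected (NA when nothing was detected).
#'
#' @param detected A [detect_transients()] result.
#' @param truth The `truth` element of a [simulate_session()] result, or a
#'   tibble `cell_id`, `event_time_s` of true events.
#' @param match_tol_s Matching tolerance in seconds (> 0).
#' @return List of class `detection_metrics`: `summary` (one-row tibble
#'   `sensitivity`, `precision`, `n_true`, `n_detected`, `n_matched`),
#'   `per_cell`, and tibbles of `unmatched_true` / `unmatched_detected`
#'   events.
#' @export
detection_metrics <- function(detected, truth, match_tol_s = 0.5) {
  check_positive(match_tol_s, "match_tol_s")
  true_events <- if (inherits(truth, "ground_truth")) truth$events else truth
  stopifnot(all(c("cell_id", "event_time_s") %in% names(true_events)))

  ids <- union(cell_levels(detected$cell_id), unique(as.character(true_events$cell_id)))
  det_by <- split(detected$event_time_s, factor(as.character(detected$cell_id), ids))
  tru_by <- split(true_events$event_time_s, factor(as.character(true_events$cell_id), ids))

  rows <- vector("list", length(ids))
  un_t <- vector("list", length(ids))
  un_d <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    d <- sort(det_by[[j]])
    tr <- sort(tru_by[[j]])
    m <- match_event_times(d, tr, match_tol_s)
    rows[[j]] <- tibble(cell_id = ids[j], n_true = length(tr),
                        n_detected = length(d), n_matched = m$n_matched)
    un_t[[j]] <- tibble(cell_id = rep(ids[j], sum(!m$matched_true)),
                        event_time_s = tr[!m$matched_true])
    un_d[[j]] <- tibble(cell_id = rep(ids[j], sum(!m$matched_det)),
                        event_time_s = d[!m$matched_det])
  }
  per_cell <- bind_rows(rows)
  n_true <- sum(per_cell$n_true)
  n_det <- sum(per_cell$n_detected)
  n_match <- sum(per_cell$n_matched)
  summary <- tibble(
    sensitivity = if (n_true > 0) n_match / n_true else NA_real_,
    precision = if (n_det > 0) n_match / n_det else NA_real_,
    n_true = n_true, n_detected = n_det, n_matched = n_match)
  structure(list(summary = summary, per_cell = per_cell,
                 unmatched_true = bind_rows(un_t),
                 unmatched_detected = bind_rows(un_d),
                 match_tol_s = match_tol_s),
            class = "detection_metrics")
}

match_event_times <- function(detected, truth, tol) {
  matched_det <- logical(length(detected))
  matched_true <- logical(length(truth))
  ti <- 1L
  for (di in seq_along(detected)) {
    while (ti <= length(truth) &&
           (matched_true[ti] || truth[ti] < detected[di] - tol)) {
      ti <- ti + 1L
    }
    if (ti <= length(truth) && abs(truth[ti] - detected[di]) <= tol) {
      matched_det[di] <- TRUE
      matched_true[ti] <- TRUE
      ti <- ti + 1L
    }
  }
  list(matched_det = matched_det, matched_true = matched_true,
       n_matched = sum(matched_det))
}

#' @export
print.detection_metrics <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<detection_metrics> sensitivity %.3f, precision %s (%d/%d true matched, %d detected; tol %.2g s)\n",
              s$sensitivity,
              ifelse(is.na(s$precision), "NA", sprintf("%.3f", s$precision)),
              s$n_matched, s$n_true, s$n_detected, x$match_tol_s))
  invisible(x)
}

#' @method glance detection_metrics
#' @export
glance.detection_metrics <- function(x, ...) x$summary

#' Circularly shift event trains (negative control)
#'
#' Shifts every cell's event train by an independent uniform offset modulo
#' the session duration, destroying any bout locking while preserving each
#' train's internal structure. Used as the shuffle null for
#' [correlate_bouts()].
#'
#' @param events A [detect_transients()] result or tibble `cell_id`,
#'   `event_time_s`.
#' @param session_duration_s Session duration (s).
#' @param seed Optional integer seed for the offsets.
#' @return Tibble with the same columns, times shifted and re-sorted within
#'   cell.
#' @export
shuffle_events <- function(events, session_duration_s, seed = NULL) {
  check_positive(session_duration_s, "session_duration_s")
  run <- function() {
    ids <- cell_levels(events$cell_id)
    offs <- runif(length(ids), 0, session_duration_s)
    names(offs) <- ids
    events |>
      mutate(event_time_s = (.data$event_time_s + offs[as.character(.data$cell_id)]) %%
               session_duration_s) |>
      arrange(.data$cell_id, .data$event_time_s)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
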