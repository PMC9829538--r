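#' Correlate transients with eating-bout onsets
#'
#' A cell counts as bout-correlated if it produced at least one detected
#' transient within `±tol_s` of any eating-bout onset falling inside the
#' analysis window `[first bout, first bout + window_s)` — 1.5 min after the
#' first bout by default. Proportions are computed over all imaged cells
#' (cells with zero transients count in the denominator).
#'
#' @param trains A [detect_transients()] result.
#' @param schedule An [event_schedule()] with at least one bout.
#' @param window_s Analysis window length after the first bout (s).
#' @param tol_s Onset tolerance (s, > 0): how close a transient must be to a
#'   bout onset to count. There is no community standard for this value; it
#'   defaults to 1 s and is always recorded in the result.
#' @param cell_ids Optional full roster of imaged cells; defaults to the
#'   cells recorded in `trains`.
#' @return Tibble `cell_id`, `n_matched_bouts`, `correlated` of class
#'   `bout_correlation`, with attributes `summary` (tibble
#'   `n_cells`, `n_correlated`, `prop_correlated`, `prop_non_correlated`,
#'   `pct_correlated`), `window`, `tol_s`, `bouts_used` and `condition`.
#' @export
correlate_bouts <- function(trains, schedule, window_s = 90, tol_s = 1,
                            cell_ids = NULL) {
  stopifnot(inherits(schedule, "event_schedule"))
  check_positive(window_s, "window_s")
  check_positive(tol_s, "tol_s")
  if (length(schedule$bout_onsets_s) == 0) {
    abort("schedule contains no eating bouts; bout correlation is undefined.",
          class = "bingetrace_no_bout_error")
  }
  first <- schedule$bout_onsets_s[1]
  window <- c(first, first + window_s)
  bouts <- schedule$bout_onsets_s[in_window(schedule$bout_onsets_s, window)]

  ids <- cell_ids %||% {
    cells <- attr(trains, "cells")
    if (!is.null(cells)) cell_levels(cells$cell_id) else cell_levels(trains$cell_id)
  }
  ids <- as.character(ids)

  ev_by <- split(trains$event_time_s, factor(as.character(trains$cell_id), ids))
  n_matched <- vapply(ev_by, function(ev) {
    if (!length(ev)) return(0L)
    sum(vapply(bouts, function(b) any(abs(ev - b) <= tol_s), logical(1)))
  }, integer(1))

  out <- tibble(cell_id = factor(ids, levels = ids),
                n_matched_bouts = unname(n_matched),
                correlated = unname(n_matched) > 0)
  n <- nrow(out)
  n_cor <- sum(out$correlated)
  summary <- tibble(
    n_cells = n, n_correlated = n_cor,
    prop_correlated = n_cor / n,
    prop_non_correlated = 1 - n_cor / n,
    pct_correlated = percent_round(c(n_cor / n, 1 - n_cor / n))[1])
  attr(out, "summary") <- summary
  attr(out, "window") <- window
  attr(out, "tol_s") <- tol_s
  attr(out, "bouts_used") <- bouts
  attr(out, "condition") <- schedule$condition
  class(out) <- c("bout_correlation", setdiff(class(out), "bout_correlation"))
  out
}

#' @method glance bout_correlation
#' @export
glance.bout_correlation <- function(x, ...) {
  bind_cols(attr(x, "summary"),
            tibble(window_start_s = attr(x, "window")[1],
                   window_s = diff(attr(x, "window")),
                   tol_s = attr(x, "tol_s")))
}

#' Extract peri-event trace segments
#'
#' Cuts each cell's \eqn{\Delta F/F_0} trace around one or more anchor times
#' (stimulus onset, first eating bout, first object contact, ...) onto a
#' common relative time axis. The anchor is mapped to the frame containing
#' it; relative time 0 is that frame. Segments extending past the session
#' are truncated with a warning.
#'
#' @param dff A [compute_dff()] result.
#' @param anchors_s Anchor times (s).
#' @param pre_s,post_s Window extent before/after each anchor (s, >= 0; the
#'   segment covers `[anchor - pre_s, anchor + post_s)`).
#' @return Tibble `cell_id`, `anchor` (index into `anchors_s`),
#'   `anchor_time_s`, `rel_time_s`, `dff`.
#' @export
peri_event_traces <- function(dff, anchors_s, pre_s, post_s) {
  stopifnot(all(c("cell_id", "time_s", "dff") %in% names(dff)))
  if (!is.numeric(anchors_s) || !length(anchors_s)) {
    abort("`anchors_s` must contain at least one anchor time.",
          class = "bingetrace_parameter_error")
  }
  if (pre_s < 0 || post_s < 0 || pre_s + post_s <= 0) {
    abort("`pre_s` and `post_s` must be non-negative and not both zero.",
          class = "bingetrace_parameter_error")
  }
  fs <- trace_frame_rate(dff)
  x_by <- split_by_cell(dff, "dff")
  n_frames <- length(x_by[[1]])
  ids <- names(x_by)
  npre <- round(pre_s * fs)
  npost <- round(post_s * fs)

  truncated <- FALSE
  segs <- vector("list", length(anchors_s))
  for (a in seq_along(anchors_s)) {
    a_idx <- floor(anchors_s[a] * fs) + 1   # frame containing the anchor
    lo <- a_idx - npre
    hi <- a_idx + npost - 1
    if (lo < 1 || hi > n_frames) {
      truncated <- TRUE
      lo <- max(1, lo)
      hi <- min(n_frames, hi)
    }
    if (hi < lo) {
      abort(sprintf("anchor %g s lies outside the session.", anchors_s[a]),
            class = "bingetrace_window_error")
    }
    rel <- (lo:hi - a_idx) / fs
    segs[[a]] <- tibble(
      cell_id = factor(rep(ids, each = length(rel)), levels = ids),
      anchor = a,
      anchor_time_s = anchors_s[a],
      rel_time_s = rep(rel, length(ids)),
      dff = unlist(lapply(x_by, function(x) x[lo:hi]), use.names = FALSE))
  }
  if (truncated) {
    warn("peri-event window extends past the session; segment(s) truncated.")
  }
  bind_rows(segs)
}
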