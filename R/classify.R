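#' Classify cells as up / down / non-response
#'
#' Applies the \eqn{\pm\sigma} rule: a cell is `up` if its mean
#' \eqn{\Delta F/F_0} over the response window (the first 2 min after the
#' stimulus by default) is strictly higher than its baseline mean plus the
#' baseline standard deviation \eqn{\sigma}, `down` if strictly lower than
#' the baseline mean minus \eqn{\sigma}, and `non_response` otherwise
#' (boundary equality included). \eqn{\sigma} and the baseline mean are
#' taken from the per-cell baseline statistics stored by [compute_dff()] —
#' one source of truth shared with the rest of the pipeline. The response
#' summary statistic is the time-average of \eqn{\Delta F/F_0} over the
#' window (`stat = "mean"`), configurable to the median.
#'
#' A cell with \eqn{\sigma = 0} (flat baseline) and a response mean
#' different from baseline is classified by the sign of the difference with
#' a warning.
#'
#' @param dff A [compute_dff()] result.
#' @param response_window Half-open interval `c(start, stop)` in seconds;
#'   must lie within the session and not overlap the baseline window.
#' @param stat `"mean"` (default) or `"median"` response summary.
#' @return Tibble `cell_id`, `baseline_mean`, `post_mean`, `sigma`,
#'   `margin` (post minus baseline, in \eqn{\sigma} units), `label`
#'   (factor up / down / non_response), of class `cell_classes`.
#' @examples
#' s <- simulate_session(scenario_config(n_cells = 6, seed = 2))
#' s$traces |> compute_dff(c(0, 120)) |> classify_cells(c(120, 240))
#' @export
classify_cells <- function(dff, response_window = c(120, 240),
                           stat = c("mean", "median")) {
  stat <- match.arg(stat)
  stopifnot(inherits(dff, "dff_traces") || all(c("cell_id", "time_s", "dff") %in% names(dff)))
  check_window(response_window, trace_session_range(dff), "response_window")
  bw <- attr(dff, "baseline_window")
  if (!is.null(bw) &&
      response_window[1] < bw[2] && bw[1] < response_window[2]) {
    abort("`response_window` overlaps the baseline window.",
          class = "bingetrace_window_error")
  }
  base <- baseline_stats(dff)

  post <- dff |>
    filter(in_window(.data$time_s, response_window)) |>
    group_by(.data$cell_id) |>
    summarise(post_mean = if (stat == "mean") mean(.data$dff) else median(.data$dff),
              .groups = "drop")
  if (nrow(post) == 0) {
    abort("`response_window` contains no frames.", class = "bingetrace_window_error")
  }

  out <- base |>
    left_join(post, by = "cell_id") |>
    mutate(
      margin = (.data$post_mean - .data$baseline_mean) / .data$sigma,
      label = case_when(
        .data$post_mean > .data$baseline_mean + .data$sigma ~ "up",
        .data$post_mean < .data$baseline_mean - .data$sigma ~ "down",
        TRUE ~ "non_response"),
      label = factor(.data$label, levels = c("up", "down", "non_response"))) |>
    select("cell_id", "baseline_mean", "post_mean", "sigma", "margin", "label")

  degen <- out$sigma == 0 & out$post_mean != out$baseline_mean
  if (any(degen)) {
    warn(paste0("zero baseline sigma for cell(s) ",
                paste(out$cell_id[degen], collapse = ", "),
                "; classified by sign of the post-baseline difference."))
  }
  class(out) <- c("cell_classes", setdiff(class(out), "cell_classes"))
  out
}

#' Summarise a cell classification
#'
#' Counts and proportions of up / down / non-response labels, with percent
#' values rounded to one decimal by largest-remainder so they sum to 100.0
#' (matching the convention of reported pie-chart percentages).
#'
#' @param labels A [classify_cells()] result (or any tibble with a `label`
#'   column).
#' @param condition Optional condition tag carried into the summary.
#' @return Tibble `label`, `n`, `prop`, `pct` with attributes `n_cells` and
#'   `condition`, of class `class_summary`.
#' @export
summarize_classes <- function(labels, condition = NULL) {
  stopifnot("label" %in% names(labels))
  if (nrow(labels) == 0) {
    abort("`labels` must contain at least one cell.",
          class = "bingetrace_parameter_error")
  }
  lv <- c("up", "down", "non_response")
  n_by <- as.integer(table(factor(labels$label, levels = lv)))
  n <- sum(n_by)
  prop <- n_by / n
  out <- tibble(
    label = factor(lv, levels = lv),
    n = n_by,
    prop = prop,
    pct = percent_round(prop))
  attr(out, "n_cells") <- n
  attr(out, "condition") <- condition
  class(out) <- c("class_summary", setdiff(class(out), "class_summary"))
  out
}
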