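#' Paired pre/post t test on per-cell means
#'
#' Two-tailed paired t test of per-cell post-anchor means against pre-anchor
#' means: with differences \eqn{d_i = post_i - pre_i},
#' \eqn{t = \bar d / (s_d / \sqrt n)} with \eqn{n - 1} degrees of freedom
#' (sample s.d.). When every difference is zero the test is vacuous and
#' returns \eqn{t = 0, p = 1}; a constant non-zero difference has no
#' within-pair variance and raises a degenerate-test error.
#'
#' @param pre_means,post_means Equal-length numeric vectors of per-cell
#'   means, `n >= 2` pairs.
#' @return Object of class `paired_ttest`: list with `statistic`, `df`,
#'   `p_value`, `n`, `mean_diff`, `sd_diff`. Has [tidy()] and [glance()]
#'   methods.
#' @examples
#' paired_pre_post_test(rnorm(20), rnorm(20))
#' @export
paired_pre_post_test <- function(pre_means, post_means) {
  if (length(pre_means) != length(post_means)) {
    abort("`pre_means` and `post_means` must have equal length.",
          class = "bingetrace_parameter_error")
  }
  n <- length(pre_means)
  df <- n - 1L
  if (n < 2) {
    abort("need at least 2 pairs.", class = "bingetrace_degenerate_test_error")
  }
  d <- post_means - pre_means
  s <- sd(d)
  if (s == 0) {
    if (all(d == 0)) {
      res <- list(statistic = 0, df = df, p_value = 1, n = n,
                  mean_diff = 0, sd_diff = 0)
      return(structure(res, class = "paired_ttest"))
    }
    abort("degenerate test: all paired differences identical and non-zero (sd = 0).",
          class = "bingetrace_degenerate_test_error")
  }
  t_stat <- mean(d) / (s / sqrt(n))
  structure(list(statistic = t_stat, df = df,
                 p_value = 2 * pt(-abs(t_stat), df = df),
                 n = n, mean_diff = mean(d), sd_diff = s),
            class = "paired_ttest")
}

#' @export
print.paired_ttest <- function(x, ...) {
  cat(sprintf("Paired t test: t_%d = %.4g, two-sided p = %.4g (n = %d pairs, mean diff %.4g)\n",
              x$df, x$statistic, x$p_value, x$n, x$mean_diff))
  invisible(x)
}

#' @rdname paired_pre_post_test
#' @param x A `paired_ttest` object.
#' @param ... Unused.
#' @method tidy paired_ttest
#' @export
tidy.paired_ttest <- function(x, ...) {
  tibble(estimate = x$mean_diff, statistic = x$statistic,
         p.value = x$p_value, parameter = x$df, n = x$n)
}

#' @rdname paired_pre_post_test
#' @method glance paired_ttest
#' @export
glance.paired_ttest <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
         n = x$n, mean_diff = x$mean_diff, sd_diff = x$sd_diff)
}

#' Build a display-ordered heat-map matrix
#'
#' Smooths each cell's \eqn{\Delta F/F_0} trace with a Gaussian filter
#' ([gaussian_smooth()]) and orders cells by descending mean smoothed
#' \eqn{\Delta F/F_0} over the post-stimulus window, the conventional
#' presentation for population responses around stimulus introduction. Ties
#' keep input order (stable sort), and the permutation is returned so rows
#' remain traceable to cells.
#'
#' @param dff A [compute_dff()] result.
#' @param schedule An [event_schedule()]; its stimulus onset anchors the
#'   sorting window, which extends to the end of the session.
#' @param smooth_sigma_s Gaussian s.d. in seconds (display only).
#' @return List of class `ca_heatmap`: `data` (long tibble `cell_id`,
#'   `time_s`, `value` with `cell_id` releveled in display order), `order`
#'   (integer permutation: row k of the display is input cell `order[k]`),
#'   `post_means`, `stimulus_onset_s`, `smooth_sigma_s`.
#' @export
make_heatmap_matrix <- function(dff, schedule, smooth_sigma_s = 0.5) {
  stopifnot(inherits(schedule, "event_schedule"))
  rng <- trace_session_range(dff)
  if (schedule$stimulus_onset_s < rng[1] || schedule$stimulus_onset_s >= rng[2]) {
    abort("stimulus onset lies outside the session.",
          class = "bingetrace_window_error")
  }
  sm <- gaussian_smooth(dff, smooth_sigma_s)
  post <- sm |>
    filter(.data$time_s >= schedule$stimulus_onset_s) |>
    group_by(.data$cell_id) |>
    summarise(post_mean = mean(.data$smoothed), .groups = "drop")
  ord <- order(-post$post_mean)   # radix sort: stable, ties keep input order
  lev_sorted <- as.character(post$cell_id)[ord]
  data <- sm |>
    transmute(cell_id = factor(.data$cell_id, levels = lev_sorted),
              time_s = .data$time_s, value = .data$smoothed)
  structure(list(data = data, order = ord,
                 post_means = post$post_mean,
                 stimulus_onset_s = schedule$stimulus_onset_s,
                 smooth_sigma_s = smooth_sigma_s),
            class = "ca_heatmap")
}

#' Configure the analysis stages
#'
#' Collects every tunable pipeline parameter with the defaults of the
#' targeted recording design: 2-min baseline and response windows around
#' the stimulus, 10-s median filter, 6-MAD detection threshold with a 2-s
#' refractory interval, 90-s bout-correlation window with ±1 s onset
#' tolerance, and 0.5-s display smoothing. The configuration (and its hash)
#' is embedded in every report for provenance.
#'
#' @param baseline_window,response_window Half-open windows `c(start, stop)`
#'   in seconds.
#' @param filter_width_s Median filter width (s).
#' @param threshold_k Detection threshold in MAD multiples.
#' @param min_interval_s Detection refractory interval (s).
#' @param bout_window_s Bout-correlation window after the first bout (s).
#' @param bout_tol_s Bout-onset tolerance (s).
#' @param smooth_sigma_s Display Gaussian s.d. (s).
#' @param match_tol_s Ground-truth matching tolerance (s), used only when
#'   scoring against a simulation.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(baseline_window = c(0, 120),
                            response_window = c(120, 240),
                            filter_width_s = 10,
                            threshold_k = 6,
                            min_interval_s = 2,
                            bout_window_s = 90,
                            bout_tol_s = 1,
                            smooth_sigma_s = 0.5,
                            match_tol_s = 0.5) {
  check_window(baseline_window, arg = "baseline_window")
  check_window(response_window, arg = "response_window")
  for (nm in c("filter_width_s", "threshold_k", "bout_window_s",
               "bout_tol_s", "smooth_sigma_s", "match_tol_s")) {
    check_positive(get(nm), nm)
  }
  if (min_interval_s < 0) {
    abort("`min_interval_s` must be non-negative.",
          class = "bingetrace_parameter_error")
  }
  structure(list(baseline_window = baseline_window,
                 response_window = response_window,
                 filter_width_s = filter_width_s,
                 threshold_k = threshold_k,
                 min_interval_s = min_interval_s,
                 bout_window_s = bout_window_s,
                 bout_tol_s = bout_tol_s,
                 smooth_sigma_s = smooth_sigma_s,
                 match_tol_s = match_tol_s),
            class = "analysis_config")
}

#' Run the full analysis pipeline on one session
#'
#' Chains every stage — \eqn{\Delta F/F_0} conversion, median detrending,
#' MAD-threshold transient detection, up/down/non-response classification,
#' bout correlation (when the schedule has bouts), the paired pre/post test
#' on per-cell window means, and heat-map ordering — and collects all
#' results with the configuration and its hash. Any stage failure aborts
#' with the stage named. Identical inputs and configuration reproduce the
#' result (and [write_report()] output) byte for byte.
#'
#' @param traces Long tibble `cell_id`, `time_s`, `fluor`.
#' @param schedule An [event_schedule()].
#' @param config An [analysis_config()].
#' @return List of class `ca_analysis` with elements `dff`, `detrended`,
#'   `events`, `classes`, `class_summary`, `bouts` (NULL when the schedule
#'   has no bouts), `paired_test`, `heatmap`, `config`, `config_hash`,
#'   `notes` (log of exclusions/decisions taken during the run).
#' @export
run_pipeline <- function(traces, schedule, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"),
            inherits(schedule, "event_schedule"))
  notes <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "bingetrace_stage_error", parent = e)
    })
  }

  dff <- stage("compute_dff", compute_dff(traces, config$baseline_window))
  detr <- stage("median_detrend", median_detrend(dff, config$filter_width_s))
  events <- stage("detect_transients",
                  detect_transients(detr, config$threshold_k, config$min_interval_s))
  classes <- stage("classify_cells", classify_cells(dff, config$response_window))
  class_summary <- stage("summarize_classes",
                         summarize_classes(classes, schedule$condition))

  bouts <- NULL
  if (length(schedule$bout_onsets_s) > 0) {
    bouts <- stage("correlate_bouts",
                   correlate_bouts(events, schedule,
                                   window_s = config$bout_window_s,
                                   tol_s = config$bout_tol_s))
  } else {
    notes <- c(notes, "no eating bouts in schedule: bout correlation skipped and its cells excluded from any bout denominator")
  }

  pre <- dff |>
    filter(in_window(.data$time_s, config$baseline_window)) |>
    group_by(.data$cell_id) |>
    summarise(m = mean(.data$dff), .groups = "drop")
  post <- dff |>
    filter(in_window(.data$time_s, config$response_window)) |>
    group_by(.data$cell_id) |>
    summarise(m = mean(.data$dff), .groups = "drop")
  paired <- stage("paired_pre_post_test", paired_pre_post_test(pre$m, post$m))

  heatmap <- stage("make_heatmap_matrix",
                   make_heatmap_matrix(dff, schedule, config$smooth_sigma_s))

  structure(list(dff = dff, detrended = detr, events = events,
                 classes = classes, class_summary = class_summary,
                 bouts = bouts, paired_test = paired, heatmap = heatmap,
                 schedule = schedule, config = config,
                 config_hash = hash(unclass(config)), notes = notes),
            class = "ca_analysis")
}

#' @export
print.ca_analysis <- function(x, ...) {
  cat(sprintf("<ca_analysis> '%s': %d cells, %d transients\n",
              x$schedule$condition, nrow(x$classes), nrow(x$events)))
  s <- x$class_summary
  cat(sprintf("  classes: up %g%% / down %g%% / non %g%%\n",
              s$pct[1], s$pct[2], s$pct[3]))
  if (!is.null(x$bouts)) {
    bs <- attr(x$bouts, "summary")
    cat(sprintf("  bout-correlated: %d/%d cells (%g%%)\n",
                bs$n_correlated, bs$n_cells, bs$pct_correlated))
  }
  cat(sprintf("  paired pre/post: t_%d = %.3f, p = %.3g\n",
              x$paired_test$df, x$paired_test$statistic, x$paired_test$p_value))
  cat(sprintf("  config hash: %s\n", x$config_hash))
  invisible(x)
}
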