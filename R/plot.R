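# ggplot2 display helpers. All plots work from pipeline outputs; none of
# them feed back into analysis.

#' @importFrom ggplot2 ggplot aes geom_raster geom_line geom_ribbon geom_col
#'   geom_vline scale_fill_viridis_c labs theme_minimal facet_wrap
#'   coord_polar theme element_blank autoplot
NULL

#' Plot an ordered response heat map
#'
#' Cells (rows) in descending order of post-stimulus mean smoothed
#' \eqn{\Delta F/F_0}; the dashed line marks stimulus introduction.
#'
#' @param object A [make_heatmap_matrix()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ca_heatmap
#' @export
autoplot.ca_heatmap <- function(object, ...) {
  ggplot(object$data, aes(x = .data$time_s, y = .data$cell_id,
                          fill = .data$value)) +
    geom_raster() +
    geom_vline(xintercept = object$stimulus_onset_s,
               linetype = "dashed", colour = "white") +
    scale_fill_viridis_c(name = expression(Delta * F / F[0])) +
    labs(x = "Time (s)", y = "Cell (sorted by post-stimulus response)") +
    theme_minimal() +
    theme(axis.text.y = element_blank(), panel.grid = element_blank())
}

#' @rdname autoplot.ca_heatmap
#' @param x A `ca_heatmap` object.
#' @param y Unused.
#' @export
plot.ca_heatmap <- function(x, y, ...) print(autoplot(x, ...))

#' Plot a classification summary
#'
#' Proportion of up / down / non-response cells as a pie chart (the
#' conventional presentation) or bar chart.
#'
#' @param summary A [summarize_classes()] result.
#' @param type `"pie"` or `"bar"`.
#' @return A ggplot.
#' @export
plot_class_summary <- function(summary, type = c("pie", "bar")) {
  type <- match.arg(type)
  p <- ggplot(summary, aes(x = if (type == "pie") "" else .data$label,
                           y = .data$prop, fill = .data$label)) +
    geom_col(width = 1, colour = "white") +
    labs(x = NULL, y = if (type == "pie") NULL else "Proportion of cells",
         fill = NULL) +
    theme_minimal()
  if (type == "pie") {
    p <- p + coord_polar(theta = "y") +
      theme(axis.text = element_blank(), panel.grid = element_blank())
  }
  p
}

#' Plot peri-event average traces
#'
#' Mean \eqn{\Delta F/F_0} across cells around each anchor, with a
#' mean ± s.e.m. ribbon.
#'
#' @param segments A [peri_event_traces()] result.
#' @return A ggplot.
#' @export
plot_peri_event <- function(segments) {
  avg <- segments |>
    group_by(.data$anchor, .data$rel_time_s) |>
    summarise(mean_dff = mean(.data$dff),
              sem = sd(.data$dff) / sqrt(dplyr::n()), .groups = "drop")
  ggplot(avg, aes(x = .data$rel_time_s, y = .data$mean_dff)) +
    geom_ribbon(aes(ymin = .data$mean_dff - .data$sem,
                    ymax = .data$mean_dff + .data$sem), alpha = 0.3) +
    geom_line() +
    geom_vline(xintercept = 0, linetype = "dashed") +
    facet_wrap(~anchor, labeller = "label_both") +
    labs(x = "Time from anchor (s)", y = expression(mean ~ Delta * F / F[0])) +
    theme_minimal()
}

#' Plot example traces
#'
#' A few cells' \eqn{\Delta F/F_0} traces stacked with a stimulus marker.
#'
#' @param dff A [compute_dff()] result.
#' @param cells Cell ids to show (default: first 4).
#' @param stimulus_onset_s Optional stimulus time for a dashed marker.
#' @return A ggplot.
#' @export
plot_traces <- function(dff, cells = NULL, stimulus_onset_s = NULL) {
  ids <- cells %||% utils::head(cell_levels(dff$cell_id), 4)
  d <- filter(dff, as.character(.data$cell_id) %in% as.character(ids))
  p <- ggplot(d, aes(x = .data$time_s, y = .data$dff)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~cell_id, ncol = 1, strip.position = "right") +
    labs(x = "Time (s)", y = expression(Delta * F / F[0])) +
    theme_minimal()
  if (!is.null(stimulus_onset_s)) {
    p <- p + geom_vline(xintercept = stimulus_onset_s, linetype = "dashed",
                        colour = "red")
  }
  p
}
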