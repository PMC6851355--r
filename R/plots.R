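#' Plot a recording trace
#'
#' @param trace A trace tibble.
#' @param downsample Keep every n-th sample for display (20 kHz traces are
#'   heavy to draw at full resolution).
#' @return A ggplot.
#' @export
plot_trace <- function(trace, downsample = 1L) {
  assert_trace(trace)
  df <- trace[seq(1, nrow(trace), by = max(1L, as.integer(downsample))), ]
  lab <- switch(trace_units(trace) %||% "au",
                pA = "current (pA)", mV = "voltage (mV)",
                dff_percent = "dF/F (%)", "fluorescence (a.u.)")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = lab) +
    ggplot2::theme_minimal()
}

#' @rdname plot_trace
#' @param object A `tone_trace`.
#' @param ... Passed to [plot_trace()].
#' @export
autoplot.tone_trace <- function(object, ...) plot_trace(object, ...)

#' Plot detected events over their trace
#'
#' @param trace The trace events were detected in.
#' @param events Event tibble from [detect_events()].
#' @param downsample Display downsampling factor.
#' @return A ggplot with event peaks marked, colored by class.
#' @export
plot_events <- function(trace, events, downsample = 10L) {
  p <- plot_trace(trace, downsample)
  if (nrow(events) == 0L) return(p)
  p + ggplot2::geom_point(
    data = events,
    ggplot2::aes(x = .data$peak_time, y = .data$amplitude, colour = .data$class),
    inherit.aes = FALSE, size = 1
  ) +
    ggplot2::labs(colour = "class")
}

#' Plot a spike/fluorescence calibration table
#'
#' Mean dF/F against injected current with the spike count as label, plus the
#' calibrated threshold if supplied.
#'
#' @param points Calibration tibble (see [calibrate_threshold()]).
#' @param threshold Optional threshold to mark, % dF/F.
#' @return A ggplot.
#' @export
plot_calibration <- function(points, threshold = NULL) {
  p <- ggplot2::ggplot(points, ggplot2::aes(x = .data$current_pa, y = .data$mean_dff)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$mean_spikes)) +
    ggplot2::labs(x = "injected current (pA)", y = "mean dF/F (%)",
                  size = "mean spikes") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  }
  p
}

#' Plot a gene-prevalence panel
#'
#' @param prevalence Tibble from [gene_prevalence()].
#' @return A ggplot bar chart of prevalence per gene.
#' @export
plot_prevalence <- function(prevalence) {
  ggplot2::ggplot(
    prevalence,
    ggplot2::aes(x = stats::reorder(.data$gene, -.data$prevalence_percent),
                 y = .data$prevalence_percent)
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "prevalence (% of cells)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
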