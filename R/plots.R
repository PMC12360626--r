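#' Plot an averaged trace
#'
#' Averaged oEPSC with the flash marked.
#'
#' @param object An `averaged_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.averaged_trace <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = 1000 * .data$time_s,
                                   y = .data$current_pa)) +
    ggplot2::geom_line(colour = "black") +
    ggplot2::geom_vline(xintercept = 1000 * object$stim_time,
                        colour = "#3070d0", linetype = "dotted") +
    ggplot2::labs(x = "Time (ms)", y = "Current (pA)",
                  title = sprintf("%s | %s (mean of %d sweeps)",
                                  object$cell_id, object$condition,
                                  object$n_sweeps_averaged)) +
    ggplot2::theme_minimal()
}

#' Event raster over latency
#'
#' One point per detected event at (latency, sweep), the raster form used
#' to compare conditions side by side.
#'
#' @param events Event tibble from [detect_events()], one or more
#'   conditions bound together.
#' @return A ggplot.
#' @export
plot_event_raster <- function(events) {
  ggplot2::ggplot(events, ggplot2::aes(x = .data$latency,
                                       y = factor(.data$sweep_index),
                                       colour = .data$condition)) +
    ggplot2::geom_point(shape = "|", size = 3) +
    ggplot2::facet_wrap(~condition, ncol = 1) +
    ggplot2::labs(x = "Latency re flash (ms)", y = "Sweep") +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}

#' Cumulative event-latency distributions
#'
#' Step ECDF of event latency per condition from [ecdf_events()] output.
#'
#' @param ecdf_tbl Tibble from [ecdf_events()].
#' @return A ggplot.
#' @export
plot_latency_ecdf <- function(ecdf_tbl) {
  ggplot2::ggplot(ecdf_tbl, ggplot2::aes(x = .data$latency, y = .data$ecdf,
                                         colour = .data$condition)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Latency re flash (ms)",
                  y = "Cumulative fraction of events") +
    ggplot2::theme_minimal()
}
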