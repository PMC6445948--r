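# ggplot2 views of the main result types.

#' Plot raw and reconstructed velocity signals with phase boundaries
#'
#' @param speeds A velocity table (possibly with several `variant`s, e.g. the
#'   `speeds` element of [run_pipeline()]'s result).
#' @param phases Optional phase table; phase boundaries are drawn as vertical
#'   lines and phase means as horizontal segments.
#' @param tracks Optional character vector of track ids to show (default:
#'   all, faceted).
#' @return A ggplot object.
#' @export
plot_velocity <- function(speeds, phases = NULL, tracks = NULL) {
  speeds <- validate_speeds(speeds)
  if (!is.null(tracks)) {
    speeds <- speeds[speeds$track_id %in% tracks, ]
    if (!is.null(phases)) phases <- phases[phases$track_id %in% tracks, ]
  }
  p <- ggplot2::ggplot(speeds, ggplot2::aes(x = .data$interval, y = .data$speed)) +
    ggplot2::geom_line(ggplot2::aes(colour = .data$variant, linewidth = .data$variant)) +
    ggplot2::scale_colour_manual(values = c(raw = "grey70", filtered = "black",
                                            true = "steelblue")) +
    ggplot2::scale_linewidth_manual(values = c(raw = 0.3, filtered = 0.7, true = 0.5),
                                    guide = "none") +
    ggplot2::facet_wrap(~track_id, scales = "free") +
    ggplot2::labs(x = "frame", y = paste0("speed (", speeds$units[1] %||% "", ")"),
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(phases) && nrow(phases) > 0) {
    p <- p +
      ggplot2::geom_vline(data = phases,
                          ggplot2::aes(xintercept = .data$start_frame),
                          colour = "red", linetype = "dashed", linewidth = 0.3) +
      ggplot2::geom_segment(
        data = phases,
        ggplot2::aes(x = .data$start_frame, xend = .data$end_frame,
                     y = .data$mean_velocity, yend = .data$mean_velocity),
        colour = "red", inherit.aes = FALSE
      )
  }
  p
}

#' Histogram of the phase-velocity distribution
#'
#' @param object A `max_velocity_result`.
#' @param phases The full phase table the result was computed from; if given,
#'   all phases are shown and the selected ones highlighted.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot max_velocity_result
#' @export
autoplot.max_velocity_result <- function(object, phases = NULL, ...) {
  df <- phases %||% object$selected
  df <- tibble::as_tibble(df)
  key <- paste(df$track_id, df$start_frame)
  sel_key <- paste(object$selected$track_id, object$selected$start_frame)
  df$selected <- key %in% sel_key
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_velocity, fill = .data$selected)) +
    ggplot2::geom_histogram(bins = 30, colour = "white") +
    ggplot2::geom_vline(xintercept = object$v_max, colour = "red") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                               name = "selected") +
    ggplot2::labs(x = "phase mean velocity", y = "phases",
                  title = sprintf("v_max = %.3g (top %.0f%% of v_sum)",
                                  object$v_max, 100 * object$fraction)) +
    ggplot2::theme_minimal()
}

#' Bar chart of a filter benchmark
#'
#' @param object A `filter_benchmark` tibble from [benchmark_filters()].
#' @param ... Unused.
#' @return A ggplot object showing mean R\eqn{^2} per filter with SD error
#'   bars.
#' @method autoplot filter_benchmark
#' @export
autoplot.filter_benchmark <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$kind <- factor(df$kind, levels = df$kind[order(-df$mean_r2)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$kind, y = .data$mean_r2)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_r2 - .data$sd_r2,
                   ymax = .data$mean_r2 + .data$sd_r2),
      width = 0.25
    ) +
    ggplot2::labs(x = NULL, y = expression(mean ~ R^2)) +
    ggplot2::theme_minimal()
}
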