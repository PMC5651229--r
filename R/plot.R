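#' Plot impulses with detected peaks
#'
#' The classic SHIMP display: head velocity in black, eye velocity in orange,
#' one panel per impulse, with the detected saccade apex marked red when
#' classified early and green when not. Traces are shown in their normalized
#' (positive head lobe) orientation when an analysis is supplied.
#'
#' @param traces Long trace tibble (see [read_shimp_csv()]).
#' @param analysis Optional [analyze_impulses()] result for peak markers.
#' @param impulses Optional character vector of impulse ids to plot (default
#'   all).
#' @param ncol Panels per row.
#' @return A ggplot object.
#' @export
plot_impulses <- function(traces, analysis = NULL, impulses = NULL, ncol = 4) {
  check_traces(traces)
  if (!is.null(impulses)) {
    traces <- traces[traces$impulse_id %in% impulses, ]
    if (!is.null(analysis)) {
      analysis <- analysis[analysis$impulse_id %in% impulses, ]
    }
  }
  if (!is.null(analysis)) {
    sgn <- stats::setNames(analysis$sign, analysis$impulse_id)
    traces <- traces |>
      dplyr::mutate(
        head_velocity_degps = .data$head_velocity_degps * sgn[.data$impulse_id],
        eye_velocity_degps = .data$eye_velocity_degps * sgn[.data$impulse_id]
      )
  }
  long <- traces |>
    tidyr::pivot_longer(
      c("head_velocity_degps", "eye_velocity_degps"),
      names_to = "channel", values_to = "velocity"
    ) |>
    dplyr::mutate(
      channel = ifelse(.data$channel == "head_velocity_degps", "head", "eye")
    )
  p <- ggplot2::ggplot(long, ggplot2::aes(
    x = .data$sample_index, y = .data$velocity, colour = .data$channel
  )) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(head = "black", eye = "darkorange")) +
    ggplot2::facet_wrap(~impulse_id, ncol = ncol) +
    ggplot2::labs(
      x = "sample", y = "angular velocity (deg/s)",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
  if (!is.null(analysis)) {
    marks <- analysis |>
      dplyr::filter(!is.na(.data$saccade_index)) |>
      dplyr::mutate(
        velocity = -.data$saccade_velocity, # marker at the trough
        classification = ifelse(.data$early, "early", "not early")
      )
    if (nrow(marks) > 0) {
      p <- p + ggplot2::geom_point(
        data = marks,
        ggplot2::aes(
          x = .data$saccade_index, y = .data$velocity,
          shape = .data$classification
        ),
        colour = ifelse(marks$early, "red", "forestgreen"),
        size = 3, inherit.aes = FALSE
      )
    }
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Latency distribution of an analyzed test
#'
#' Histogram of per-impulse saccade latencies coloured by early/not-early
#' classification.
#'
#' @param object A `shimp_analysis` tibble.
#' @param binwidth_ms Histogram bin width (ms).
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot shimp_analysis
#' @export
autoplot.shimp_analysis <- function(object, binwidth_ms = 20, ...) {
  d <- object |>
    dplyr::filter(!is.na(.data$latency_ms)) |>
    dplyr::mutate(classification = ifelse(.data$early, "early", "not early"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$latency_ms, fill = .data$classification)) +
    ggplot2::geom_histogram(binwidth = binwidth_ms, boundary = 0) +
    ggplot2::scale_fill_manual(values = c("early" = "red", "not early" = "forestgreen")) +
    ggplot2::labs(x = "first-saccade latency (ms)", y = "impulses", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Protocol comparison plot
#'
#' Per-protocol mean first-saccade latency as a point range (mean of per-test
#' means).
#'
#' @param object A `shimp_protocol_comparison` from
#'   [compare_protocol_means()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot shimp_protocol_comparison
#' @export
autoplot.shimp_protocol_comparison <- function(object, ...) {
  ggplot2::ggplot(object$means, ggplot2::aes(
    x = .data$protocol, y = .data$mean_latency_ms
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "mean first-saccade latency (ms)") +
    ggplot2::theme_minimal()
}
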