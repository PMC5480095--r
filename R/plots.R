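# ggplot2 displays for the main result types.

#' Plot calcium traces
#'
#' dF/F0 traces stacked with a vertical offset; the glutamate window, when
#' present, is shaded.
#'
#' @param object A [calcium_recording()].
#' @param offset Vertical offset between traces (dF/F0 units).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.calcium_recording <- function(object, offset = 1, ...) {
  dff <- delta_f_over_f(object)
  n <- nrow(dff)
  df <- tibble::tibble(
    cell = factor(rep(object$cell_ids, each = ncol(dff))),
    time_s = rep((seq_len(ncol(dff)) - 1) / object$fps, n),
    dff = as.vector(t(dff)) + rep((seq_len(n) - 1) * offset, each = ncol(dff))
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$dff,
                                        group = .data$cell)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "dF/F0 (offset per cell)") +
    ggplot2::theme_minimal()
  if (!is.null(object$stim_window)) {
    p <- p + ggplot2::annotate(
      "rect", xmin = (object$stim_window[1] - 1) / object$fps,
      xmax = object$stim_window[2] / object$fps,
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "red")
  }
  p
}

#' Plot a kymograph
#'
#' Position along the path against time; moving comets appear as sloped
#' streaks.
#'
#' @param object A [kymograph()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kymograph <- function(object, ...) {
  df <- expand.grid(position_px = seq_len(nrow(object$map)),
                    frame = seq_len(ncol(object$map)))
  df$intensity <- as.vector(object$map)
  ggplot2::ggplot(df, ggplot2::aes(.data$frame, .data$position_px,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = sprintf("frame (%g s each)", object$frame_interval_s),
                  y = "position along path (px)") +
    ggplot2::theme_minimal()
}

#' Bar chart of per-well metric means by treatment
#'
#' Mean + standard deviation across wells per treatment group, the standard
#' presentation of high-content well summaries.
#'
#' @param wells A `well_summary` tibble from [aggregate_per_well()] joined
#'   with treatment labels.
#' @param metric_name Metric to display.
#' @return A ggplot object.
#' @export
plot_well_summary <- function(wells, metric_name) {
  stopifnot("treatment" %in% names(wells))
  df <- wells |>
    dplyr::filter(.data$metric == metric_name, is.finite(.data$mean)) |>
    dplyr::group_by(.data$treatment) |>
    dplyr::summarise(m = base::mean(.data$mean),
                     s = stats::sd(.data$mean), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$treatment, .data$m)) +
    ggplot2::geom_col(fill = "grey70", colour = "black", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$m,
                                        ymax = .data$m + .data$s),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = metric_name) +
    ggplot2::theme_classic()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
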