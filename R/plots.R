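# ggplot2 visualizations of the pipeline's result types.

#' Raster plot of spike times by unit
#'
#' @param units Units tibble from [sort_recording()] (or any tibble with
#'   `unit_id`/`unit` and a `spike_times` list-column).
#' @return A ggplot.
#' @export
plot_raster <- function(units) {
  id_col <- if ("unit_id" %in% names(units)) "unit_id" else "unit"
  df <- tidyr::unnest(
    dplyr::select(units, unit = dplyr::all_of(id_col), "spike_times"),
    "spike_times")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$spike_times,
                                   y = factor(.data$unit))) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::labs(x = "Time (s)", y = "Unit") +
    ggplot2::theme_minimal()
}

#' Plot a peri-event histogram of CAPs around burst onsets
#'
#' @param object A `cap_peh` tibble from [peri_event_hist()].
#' @param burst_dur_ms Optional mean burst duration overlay, ms.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cap_peh <- function(object, burst_dur_ms = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$lag_mid * 1000,
                                    y = .data$count)) +
    ggplot2::geom_col(width = 1000 * (object$lag_hi[1] - object$lag_lo[1]),
                      fill = "grey30") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Lag from burst onset (ms)", y = "Summed CAP count") +
    ggplot2::theme_minimal()
  if (!is.null(burst_dur_ms)) {
    p <- p + ggplot2::annotate("rect", xmin = 0, xmax = burst_dur_ms,
                               ymin = -Inf, ymax = Inf, alpha = 0.15,
                               fill = "purple")
  }
  p
}

#' Plot a peak-ordered normalized firing heatmap
#'
#' @param object A `cap_heatmap` matrix from [heatmap_matrix()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cap_heatmap <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object), rownames = "unit_id") |>
    tidyr::pivot_longer(-"unit_id", names_to = "bin_start",
                        values_to = "rate") |>
    dplyr::mutate(bin_start = as.numeric(.data$bin_start),
                  unit_id = factor(.data$unit_id,
                                   levels = rev(attr(object, "order"))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_start / 60,
                                   y = .data$unit_id,
                                   fill = .data$rate)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "Normalized\nrate") +
    ggplot2::labs(x = "Time (min)", y = "Unit (peak-time ordered)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot decoder posteriors and decoded classes over time
#'
#' One panel per class showing the posterior probability trace; points mark
#' the decoded (argmax) class of each timepoint.
#'
#' @param object A `cap_decode` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cap_decode <- function(object, ...) {
  df <- object$posteriors |>
    tidyr::pivot_longer(dplyr::all_of(c("p_BL", "p_TNF", "p_IL1B")),
                        names_to = "class", values_to = "posterior") |>
    dplyr::mutate(class = factor(sub("^p_", "", .data$class),
                                 levels = c("BL", "TNF", "IL1B")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_s / 60,
                                   y = .data$posterior,
                                   colour = .data$class)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.6) +
    ggplot2::facet_wrap(~class, ncol = 1) +
    ggplot2::labs(x = "Time (min)", y = "Posterior probability") +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}
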