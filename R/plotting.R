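#' Spatiotemporal pressure map of a recording
#'
#' The standard HRCM display: time on x, sensors on y with the distal end
#' (P1, closest to the anus) at the bottom, pressure as color. Malfunctioning
#' sensors are rendered in a neutral gray. The map is deterministic for a
#' fixed recording and window; the time axis is decimated to at most
#' `max_cols` columns for display.
#'
#' @param object an `hrcm_recording`.
#' @param from_s,to_s time window, s.
#' @param max_cols maximum time bins in the raster.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.hrcm_recording <- function(object, from_s = 0,
                                    to_s = recording_duration(object),
                                    max_cols = 2000, ...) {
  if (to_s <= from_s) stop("empty window", call. = FALSE)
  fs <- object$sampling_rate
  i0 <- max(1L, floor(from_s * fs) + 1L)
  i1 <- min(ncol(object$pressures), ceiling(to_s * fs))
  idx <- unique(round(seq(i0, i1, length.out = min(max_cols, i1 - i0 + 1L))))
  m <- object$pressures[, idx, drop = FALSE]
  m[!object$functional_mask, ] <- NA
  df <- tidyr::expand_grid(sensor = seq_len(object$n_sensors),
                           col = seq_along(idx)) |>
    dplyr::mutate(time_s = (idx[.data$col] - 1) / fs,
                  pressure = as.vector(m[cbind(.data$sensor, .data$col)]))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$sensor,
                                   fill = .data$pressure)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "inferno", na.value = "grey60",
                                  name = "mmHg") +
    ggplot2::scale_y_continuous(breaks = c(1, seq(6, object$n_sensors, 6)),
                                expand = c(0, 0)) +
    ggplot2::scale_x_continuous(expand = c(0, 0)) +
    ggplot2::labs(x = "time (s)", y = "sensor (P1 distal at bottom)",
                  title = object$subject_id) +
    ggplot2::theme_minimal()
}

#' Render a spatiotemporal map to an image file
#'
#' @param rec an `hrcm_recording`.
#' @param from_s,to_s time window, s.
#' @param out output image path (`.png` or `.svg`).
#' @param width,height,dpi passed to [ggplot2::ggsave()].
#' @return `out`, invisibly.
#' @export
render_map <- function(rec, from_s = 0, to_s = recording_duration(rec), out,
                       width = 8, height = 5, dpi = 150) {
  p <- autoplot.hrcm_recording(rec, from_s, to_s)
  ggplot2::ggsave(out, p, width = width, height = height, dpi = dpi)
  invisible(out)
}

#' Timeline plot of classified events
#'
#' One horizontal segment per event spanning its sensors over time, colored
#' by class.
#'
#' @param events event tibble from [detect_events()].
#' @return a ggplot object.
#' @export
plot_events <- function(events) {
  ggplot2::ggplot(events,
                  ggplot2::aes(x = .data$onset_s,
                               xend = .data$onset_s + .data$duration_s,
                               y = .data$first_sensor,
                               yend = .data$last_sensor,
                               colour = .data$kind)) +
    ggplot2::geom_segment(linewidth = 1.2) +
    ggplot2::labs(x = "time (s)", y = "sensor", colour = "pattern") +
    ggplot2::theme_minimal()
}
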