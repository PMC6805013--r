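# ggplot2 displays for the main result types

#' @method autoplot edge_map
#' @export
autoplot.edge_map <- function(object, ...) {
  df <- tidy.edge_map(object)
  lab <- if (attr(object, "kind") == "velocity") {
    "edge velocity (µm/s)"
  } else {
    "edge fluorescence (a.u.)"
  }
  ggplot(df, aes(x = .data$t_s, y = .data$frac, fill = .data$value)) +
    geom_raster() +
    scale_fill_gradient2(low = "#313695", mid = "white", high = "#a50026",
                         name = lab) +
    labs(x = "time (s)", y = "boundary position (fraction)") +
    theme_minimal()
}

#' @method autoplot edge_xcorr_pooled
#' @export
autoplot.edge_xcorr_pooled <- function(object, ...) {
  ggplot(object, aes(x = .data$offset_s, y = .data$mean_r)) +
    geom_ribbon(aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                fill = "grey80") +
    geom_line() +
    geom_vline(xintercept = attr(object, "peak_offset_s"),
               linetype = "dashed", colour = "red") +
    labs(
      x = "temporal offset (s)",
      y = "Pearson r (velocity vs fluorescence)"
    ) +
    theme_minimal()
}

#' @method autoplot polarity_trace
#' @export
autoplot.polarity_trace <- function(object, ...) {
  ggplot(object$summary, aes(x = .data$t_s, y = .data$mean_distance)) +
    geom_ribbon(aes(ymin = .data$ci_lo_distance, ymax = .data$ci_hi_distance),
                fill = "grey80") +
    geom_line() +
    labs(x = "time since stimulus (s)", y = "polarity (normalized distance)") +
    theme_minimal()
}

#' @method autoplot motility_summary
#' @export
autoplot.motility_summary <- function(object, ...) {
  ggplot(object$msd, aes(x = .data$lag_s, y = .data$msd)) +
    geom_ribbon(aes(ymin = .data$ci_lo, ymax = .data$ci_hi), fill = "grey80") +
    geom_line() +
    geom_point() +
    labs(x = "time interval (s)", y = expression(MSD ~ (mu * m^2))) +
    theme_minimal()
}

#' @method autoplot mc_ensemble
#' @export
autoplot.mc_ensemble <- function(object, ...) {
  ggplot(object, aes(x = .data$asphericity)) +
    geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    labs(x = "asphericity", y = "states") +
    theme_minimal()
}

#' Plot cell trajectories normalized to a common origin
#'
#' @param tracks a `cell_tracks` tibble.
#' @return a ggplot.
#' @export
plot_trajectories <- function(tracks) {
  df <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::mutate(
      x0 = .data$x_um - .data$x_um[1],
      y0 = .data$y_um - .data$y_um[1]
    ) |>
    dplyr::ungroup()
  ggplot(df, aes(.data$x0, .data$y0, group = .data$track_id,
                 colour = factor(.data$track_id))) +
    geom_path(show.legend = FALSE) +
    coord_equal() +
    labs(x = "x (µm)", y = "y (µm)") +
    theme_minimal()
}

#' Overlay detected reversals on a velocity kymograph
#'
#' @param vel an [edge_map()] of kind `"velocity"`.
#' @param events a `reversal_events` tibble.
#' @return a ggplot.
#' @export
plot_reversals <- function(vel, events) {
  dt <- attr(vel, "frame_interval")
  autoplot.edge_map(vel) +
    geom_point(
      data = tibble(
        t_s = (events$frame - 1) * dt, frac = events$frac
      ),
      aes(x = .data$t_s, y = .data$frac),
      inherit.aes = FALSE, shape = 4, size = 2, stroke = 1.2
    )
}
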