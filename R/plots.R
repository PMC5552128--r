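#' Plot the embedded movement-pattern space
#'
#' Scatter of the first two Laplacian-eigenmap coordinates, colored by
#' movement-pattern label; unclustered (noise) windows — the unstable
#' movement pattern — are drawn in blue.
#'
#' @param object A `window_labeling`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.window_labeling <- function(object, ...) {
  df <- tibble::tibble(
    e1 = object$embedding[, 1], e2 = object$embedding[, 2],
    label = factor(object$windows$label)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$e1, .data$e2, color = .data$label)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_color_manual(
      values = c("0" = "steelblue"),
      na.value = "grey40",
      breaks = levels(df$label),
      guide = ggplot2::guide_legend(title = "pattern")
    ) +
    ggplot2::labs(
      x = "eigenmap 1", y = "eigenmap 2",
      title = "Movement patterns in the embedded feature space"
    ) +
    ggplot2::theme_minimal()
}

#' Plot grid summaries against the sensor ratio
#'
#' @param object An `experiment_summary`.
#' @param ... Unused.
#' @return A ggplot with one panel per summary quantity.
#' @export
autoplot.experiment_summary <- function(object, ...) {
  df <- object$conditions |>
    tidyr::pivot_longer(
      c("mean_patterns", "mean_stable", "mean_max_duration"),
      names_to = "quantity", values_to = "value"
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$alpha, .data$value,
    color = factor(.data$z)
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(
      x = "sensor ratio", y = NULL, color = "tonic input",
      title = "Movement-pattern statistics across the sensor-ratio grid"
    ) +
    ggplot2::theme_minimal()
}

#' Plot joint-angle traces of a trajectory
#'
#' @param traj A trajectory tibble.
#' @param joints Joint indices to draw.
#' @param time_range Optional `c(from, to)` window (s).
#' @return A ggplot.
#' @export
plot_joint_angles <- function(traj, joints = 1:4, time_range = NULL) {
  cols <- paste0("theta", joints)
  df <- dplyr::select(
    tibble::as_tibble(traj), "time",
    dplyr::all_of(cols)
  ) |>
    tidyr::pivot_longer(-"time", names_to = "joint", values_to = "angle")
  if (!is.null(time_range)) {
    df <- dplyr::filter(
      df, .data$time >= time_range[1],
      .data$time <= time_range[2]
    )
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$angle, color = .data$joint)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "joint angle (rad)") +
    ggplot2::theme_minimal()
}
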