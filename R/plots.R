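#' Plot observed condition means against model predictions
#'
#' Observed per-condition mean responses (points, with +/- 1 SD error bars)
#' overlaid with the fitted model's predicted mean response across the
#' visual-tilt range, faceted by task and head condition and coloured by
#' platform tilt.
#'
#' @param object An `observer_fit`.
#' @param n_grid Number of visual-tilt grid points for the prediction curves.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot observer_fit
#' @export
autoplot.observer_fit <- function(object, n_grid = 101, ...) {
  trials <- object$trials
  obs <- trials |>
    dplyr::group_by(
      .data$task, .data$block, .data$head_tilted,
      .data$platform_tilt_deg, .data$ar_tilt_deg
    ) |>
    dplyr::summarise(
      mean_response = mean(.data$response_deg),
      sd_response = stats::sd(.data$response_deg),
      .groups = "drop"
    )
  grid <- tidyr::expand_grid(
    task = unique(trials$task),
    block = unique(trials$block),
    platform_tilt_deg = unique(trials$platform_tilt_deg),
    ar_tilt_deg = seq(min(trials$ar_tilt_deg), max(trials$ar_tilt_deg),
      length.out = n_grid
    )
  ) |>
    dplyr::mutate(head_tilted = as.integer(.data$block == "tilted"))
  grid <- predict_trials(grid, object$params, object$variant)

  ggplot2::ggplot(
    obs,
    ggplot2::aes(
      x = .data$ar_tilt_deg, y = .data$mean_response,
      colour = factor(.data$platform_tilt_deg)
    )
  ) +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean_response - .data$sd_response,
        ymax = .data$mean_response + .data$sd_response
      ),
      width = 2, alpha = 0.6
    ) +
    ggplot2::geom_point() +
    ggplot2::geom_line(
      data = grid,
      ggplot2::aes(y = .data$pred_mean_deg),
      linewidth = 0.4
    ) +
    ggplot2::facet_grid(task ~ block, scales = "free_y") +
    ggplot2::labs(
      x = "commanded visual tilt (deg)",
      y = "response (deg)",
      colour = "platform tilt (deg)",
      title = sprintf(
        "participant %s, variant \"%s\"",
        object$participant_id, object$variant
      )
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the reliability-based weights across visual tilt
#'
#' Shows how the direct-path weights of the head-in-space and body-in-space
#' estimates fall with visual-tilt eccentricity for a given observer.
#'
#' @param params An [observer_params] object.
#' @param ar_range Range of commanded visual tilt (deg).
#' @return A ggplot object.
#' @export
plot_weight_profile <- function(params, ar_range = c(-36, 36)) {
  grid <- seq(ar_range[1], ar_range[2], length.out = 145)
  w <- observer_weights(params, grid) |>
    tidyr::pivot_longer(c("omega_hisd", "omega_bisd"),
      names_to = "weight", values_to = "value"
    )
  ggplot2::ggplot(w, ggplot2::aes(.data$ar_tilt_deg, .data$value,
    colour = .data$weight
  )) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_discrete(
      labels = c(omega_bisd = "body direct", omega_hisd = "head direct")
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "commanded visual tilt (deg)",
      y = "weight on the direct estimate",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}
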