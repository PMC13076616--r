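#' Tidy a genetic-algorithm run
#'
#' @param x An `emd_run`.
#' @param ... Unused.
#' @return Tibble with one row per generation: `generation`,
#'   `best_fitness`, `best_dsi`.
#' @export
tidy.emd_run <- function(x, ...) {
  x$history
}

#' One-row summary of a genetic-algorithm run
#'
#' @param x An `emd_run`.
#' @param ... Unused.
#' @return Tibble with `generations`, `best_fitness`, `mean_dsi`, `seed`.
#' @export
glance.emd_run <- function(x, ...) {
  tibble(generations = max(x$history$generation),
         best_fitness = x$best_eval$fitness,
         mean_dsi = x$best_eval$mean_dsi,
         seed = x$seed %||% NA_integer_)
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' @export
#' @importFrom ggplot2 autoplot
ggplot2::autoplot

#' Directional tuning table of an evolved circuit
#'
#' @param run An `emd_run`.
#' @return Tibble with `direction` (radians), `speed` (mm/s; spatial period
#'   for grating protocols) and `response`.
#' @export
directional_tuning <- function(run) {
  R <- run$best_eval$R
  conds <- if (run$chassis$protocol == "grating") run$chassis$periods else run$chassis$speeds
  tibble(direction = rep(run$chassis$directions, times = ncol(R)),
         speed = rep(conds, each = nrow(R)),
         response = as.vector(R))
}

#' Plot the fitness trajectory of a run
#'
#' @param object An `emd_run`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.emd_run <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(.data$generation, .data$best_fitness)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "generation", y = "best directional metric",
                  title = "Elitist GA fitness trajectory") +
    ggplot2::theme_minimal()
}

#' Polar plot of directional tuning
#'
#' @param run An `emd_run`.
#' @return A ggplot in polar coordinates, one line per speed.
#' @export
plot_tuning <- function(run) {
  df <- directional_tuning(run)
  df <- bind_rows(df, df |> filter(.data$direction == min(.data$direction)) |>
                    mutate(direction = .data$direction + 2 * pi))
  ggplot2::ggplot(df, ggplot2::aes(.data$direction, .data$response,
                                   color = factor(.data$speed))) +
    ggplot2::geom_line() +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::labs(x = NULL, y = "peak response", color = "speed (mm/s)") +
    ggplot2::theme_minimal()
}

#' Plot a space-time receptive-field map
#'
#' Depolarizing fluctuations are shown in green and hyperpolarizing ones in
#' red, over bar position (vertical) and time since bar onset (horizontal).
#'
#' @param object An `emd_spacetime`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.emd_spacetime <- function(object, ...) {
  df <- expand.grid(position = object$positions, time = object$times)
  df$response <- as.vector(object$map)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$position,
                                   fill = .data$response)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "black",
                                  high = "springgreen3") +
    ggplot2::labs(x = "time after bar onset (ms)", y = "bar position (um)",
                  fill = "mV") +
    ggplot2::theme_minimal()
}

#' Scatter of circuits in the primitive plane
#'
#' @param coords Tibble of primitive coordinates (from
#'   [classify_primitives()] over several circuits) with columns `x`, `y`
#'   and optionally `dsi` for color.
#' @param threshold Presence threshold drawn as a reference box.
#' @return A ggplot.
#' @export
plot_primitive_space <- function(coords, threshold = 0.2) {
  p <- ggplot2::ggplot(coords, ggplot2::aes(.data$x, .data$y))
  if ("dsi" %in% names(coords)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(color = .data$dsi))
  } else {
    p <- p + ggplot2::geom_point()
  }
  p +
    ggplot2::annotate("rect", xmin = -threshold, xmax = threshold,
                      ymin = -threshold, ymax = threshold, alpha = 0.1) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::coord_equal(xlim = c(-1, 1), ylim = c(-1, 1)) +
    ggplot2::labs(x = "kinetic axis", y = "overlap axis") +
    ggplot2::theme_minimal()
}
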