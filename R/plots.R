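#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fluctuation trajectory
#'
#' Time course of the reconstructed totals, active-cofactor species in red
#' and inactive in blue, matching the published panel style.
#'
#' @param object A `"fluct_traj"` tibble.
#' @param t_max Upper time limit to display (default 200, the published
#'   panel range).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fluct_traj <- function(object, t_max = 200, ...) {
  df <- dplyr::filter(object, .data$t <= t_max) |>
    tidyr::pivot_longer(c("X_total", "Z_total"),
                        names_to = "species", values_to = "concentration")
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$concentration,
                                   colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(X_total = "red", Z_total = "blue"),
                                 labels = c("X", "Z")) +
    ggplot2::labs(x = "t", y = "concentration", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Phase-plane plot of a trajectory
#'
#' @param traj A `"fluct_traj"` tibble.
#' @return A ggplot object of the `(X, Z)` orbit.
#' @export
plot_orbit <- function(traj) {
  ggplot2::ggplot(orbit(traj), ggplot2::aes(.data$X_total, .data$Z_total)) +
    ggplot2::geom_path(alpha = 0.7) +
    ggplot2::labs(x = "X", y = "Z") +
    ggplot2::theme_minimal()
}

#' Plot a log-scaling fit
#'
#' @param object A `"log_fit"` object.
#' @param ... Unused.
#' @return A ggplot object: metric against `ln(eps)` with the fitted line.
#' @export
autoplot.log_fit <- function(object, ...) {
  df <- tibble::tibble(leps = log(object$eps_grid), metric = object$metric)
  ggplot2::ggplot(df, ggplot2::aes(.data$leps, .data$metric)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = "ln(eps)", y = "metric") +
    ggplot2::theme_minimal()
}

#' Plot a bifurcation diagram of the reduced equation
#'
#' Equilibrium branches `v(eps)` of the reduced slow-mode equation; nonzero
#' branches solid, the quiescent branch dashed.
#'
#' @param object A `"bifurcation"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bifurcation <- function(object, ...) {
  ggplot2::ggplot(object$branches,
                  ggplot2::aes(.data$eps, .data$v, group = .data$nonzero,
                               linetype = .data$nonzero)) +
    ggplot2::geom_point(size = 0.5) +
    ggplot2::geom_vline(xintercept = object$eps_star, colour = "grey50",
                        linetype = "dotted") +
    ggplot2::labs(x = "eps = p - p_c", y = "v equilibrium") +
    ggplot2::theme_minimal()
}
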