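#' Plot tuning curves of a population
#'
#' @param pop A `tuning_population`.
#' @param n_show Number of randomly chosen neurons to display.
#' @param n_points Stimulus resolution.
#' @param seed Seed for the neuron subsample.
#' @return A ggplot object.
#' @export
plot_tuning_curves <- function(pop, n_show = 20, n_points = 200, seed = 1) {
  stopifnot(inherits(pop, "tuning_population"))
  ids <- if (nrow(pop) > n_show) {
    withr::with_seed(as.integer(seed), sample(pop$neuron_id, n_show))
  } else {
    pop$neuron_id
  }
  sub <- dplyr::filter(tibble::as_tibble(pop), .data$neuron_id %in% ids)
  grid <- seq(0, 2 * pi, length.out = n_points)
  curves <- tidyr::expand_grid(sub, s = grid)
  curves <- dplyr::mutate(
    curves,
    rate = vonmises_curve(.data$s, .data$rho, .data$upsilon, .data$beta, .data$phi)
  )
  ggplot2::ggplot(curves, ggplot2::aes(.data$s, .data$rate,
                                       group = .data$neuron_id)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "stimulus (rad)", y = "mean rate") +
    ggplot2::theme_minimal()
}

#' Plot output information against the output-noise variance
#'
#' Visualizes a [run_noise_sweep()] result: stimulus-averaged output
#' information for the aligned and tilted populations as the iid output-noise
#' variance grows.
#'
#' @param results A `popinfo_noise_sweep` tibble.
#' @return A ggplot object.
#' @export
plot_noise_sweep <- function(results) {
  stopifnot(inherits(results, "popinfo_noise_sweep"))
  df <- dplyr::filter(tibble::as_tibble(results), .data$sigma2 > 0)
  ggplot2::ggplot(df, ggplot2::aes(.data$sigma2, .data$I_y,
                                   colour = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(sigma^2), y = expression(I[y]),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot spiking-layer information against the rank-one noise strength
#'
#' Visualizes a [run_dg_sweep()] result: Monte Carlo output information (with
#' +/- 2 standard-error ribbons) versus `eps_u`, one panel per pre-threshold
#' noise level, colored by tilt angle.
#'
#' @param results A `popinfo_dg_sweep` tibble.
#' @return A ggplot object.
#' @export
plot_dg_sweep <- function(results) {
  stopifnot(inherits(results, "popinfo_dg_sweep"))
  df <- dplyr::mutate(tibble::as_tibble(results),
                      theta = factor(.data$theta_u))
  ggplot2::ggplot(df, ggplot2::aes(.data$eps_u, .data$I_y_mean,
                                   colour = .data$theta, group = .data$theta)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$I_y_mean - 2 * .data$mc_se,
                                      ymax = .data$I_y_mean + 2 * .data$mc_se,
                                      fill = .data$theta),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~sigma_zeta2, labeller = ggplot2::label_both) +
    ggplot2::labs(x = expression(epsilon[u]), y = expression(I[y]),
                  colour = expression(theta[u]), fill = expression(theta[u])) +
    ggplot2::theme_minimal()
}
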