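#' Plot ensemble population dynamics
#'
#' Singlet and triplet population traces over time, one line per scalar
#' state, plus the summed triplet population.
#'
#' @param object A `population_series` from [ensemble_populations()].
#' @param total_triplet Overlay the summed triplet population. Default TRUE.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.population_series <- function(object, total_triplet = TRUE, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$t_fs, y = .data$population,
                                    colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (fs)", y = "population",
                  title = paste0("ensemble populations (alpha = ",
                                 attr(object, "alpha"), ", n = ",
                                 attr(object, "n_traj"), ")")) +
    ggplot2::ylim(0, 1)
  if (total_triplet) {
    tt <- population_of(object, "triplets")
    p <- p + ggplot2::geom_line(data = tt,
                                ggplot2::aes(x = .data$t_fs, y = .data$population),
                                inherit.aes = FALSE, linewidth = 1,
                                linetype = "dashed")
  }
  p
}

#' Plot a nuclear-ensemble absorption spectrum
#'
#' @param object A `nea_spectrum` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nea_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$energy_eV,
                                       y = .data$cross_section)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "photon energy (eV)", y = "cross-section (arb. units)",
                  title = paste0("nuclear-ensemble spectrum (",
                                 attr(object, "n_configs"), " configurations)"))
}

#' Plot a lifetime extrapolation to the unscaled coupling
#'
#' Log-log scatter of the fitted lifetimes against the SOC scaling factor
#' with the free-slope regression line extended to alpha = 1.
#'
#' @param object An `alpha_extrapolation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.alpha_extrapolation <- function(object, ...) {
  pts <- tibble::tibble(alpha = object$alphas, tau_fs = object$taus_fs)
  la <- seq(0, log10(max(object$alphas)) * 1.05, length.out = 50)
  line <- tibble::tibble(alpha = 10^la,
                         tau_fs = 10^(object$intercept + object$slope * la))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$alpha, y = .data$tau_fs)) +
    ggplot2::geom_line(data = line, colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_point(data = tibble::tibble(alpha = 1, tau_fs = object$tau1_fs),
                        shape = 1, size = 3) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "SOC scaling factor alpha", y = "lifetime (fs)",
                  title = sprintf("extrapolation: tau(1) = %.3g ps (slope %.2f)",
                                  object$tau1_fs / 1000, object$slope))
}

#' Plot an angular occurrence histogram
#'
#' @param object An `angle_histogram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.angle_histogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_mid, y = .data$count)) +
    ggplot2::geom_col(width = attr(object, "bin_width_deg")) +
    ggplot2::labs(x = "dihedral angle (degrees)", y = "occurrence",
                  title = attr(object, "label"))
}
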