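#' ggplot2 views of the analysis results
#'
#' Every profile result has an `autoplot()` method; `plot_spectrum_fit()`
#' overlays the Helfrich fit on the measured spectrum and
#' `plot_tilt_free_energy()` shows the Boltzmann-inverted tilt free energy
#' with its quadratic fit.
#'
#' @name plots
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method ggplot2::autoplot
autoplot.scd_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$carbon, y = .data$abs_scd)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$abs_scd - .data$se, ymax = .data$abs_scd + .data$se)) +
    ggplot2::labs(x = "carbon index (head to tail)", y = "|SCD|",
                  title = "Deuterium order parameter profile") +
    ggplot2::ylim(0, NA)
}

#' @exportS3Method ggplot2::autoplot
autoplot.gauche_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dihedral_index, y = .data$gauche)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$gauche - .data$se, ymax = .data$gauche + .data$se)) +
    ggplot2::labs(x = "dihedral index", y = "gauche fraction",
                  title = "Gauche conformer fraction profile") +
    ggplot2::ylim(0, NA)
}

#' @exportS3Method ggplot2::autoplot
autoplot.cavity_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$z, y = .data$pcav)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z from bilayer center (nm)", y = "P_cav",
                  title = "Cavity density profile")
}

#' @exportS3Method ggplot2::autoplot
autoplot.fluctuation_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$q, y = .data$h2)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "q (1/nm)", y = expression(L[x] * L[y] ~ "<|h(q)|"^2 * "> (nm"^4 * ")"),
                  title = "Height-fluctuation spectrum")
}

#' @exportS3Method ggplot2::autoplot
autoplot.free_energy_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$z, y = .data$dG)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$dG - .data$se, ymax = .data$dG + .data$se)) +
    ggplot2::labs(x = "z from bilayer center (nm)", y = expression(Delta * G ~ "(kJ/mol)"),
                  title = "Permeation free energy (thermodynamic integration)")
}

#' @exportS3Method ggplot2::autoplot
autoplot.diffusivity_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$z, y = .data$D)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "z from bilayer center (nm)", y = expression(D(z) ~ "(cm"^2 * "/s)"),
                  title = "Local diffusivity profile")
}

#' @exportS3Method ggplot2::autoplot
autoplot.resistance_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$z, y = .data$r_local)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "z from bilayer center (nm)",
                  y = expression(R[local](z) ~ "(s/cm"^2 * ")"),
                  title = "Local permeation resistance")
}

#' @exportS3Method ggplot2::autoplot
autoplot.bending_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$z, y = .data$e_bend)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$e_bend - .data$se, ymax = .data$e_bend + .data$se)) +
    ggplot2::labs(x = "permeant z (nm)", y = expression(Delta * E[bend] ~ "(kJ/mol)"),
                  title = "Membrane bending-energy profile")
}

#' Spectrum with the fitted Helfrich law overlaid
#'
#' @param fit a `spectrum_fit` from [bending_modulus_spectrum()]
#' @return a ggplot
#' @export
plot_spectrum_fit <- function(fit) {
  stopifnot(inherits(fit, "spectrum_fit"))
  sp <- fit$spectrum
  qs <- exp(seq(log(min(sp$q[sp$q > 0])), log(max(sp$q)), length.out = 200))
  curve <- tibble::tibble(q = qs, h2 = 1 / (fit$kc * qs^4 + fit$chi_s * qs^2))
  autoplot(sp) +
    ggplot2::geom_line(data = curve, colour = "red") +
    ggplot2::geom_vline(xintercept = fit$q_cut, linetype = "dashed") +
    ggplot2::labs(subtitle = sprintf("KC = %.1f kBT, chi_s = %.2f kBT/nm^2",
                                     fit$kc, fit$chi_s))
}

#' Tilt free energy with its quadratic fit
#'
#' @param fit a `tilt_fit` from [tilt_modulus()]
#' @return a ggplot
#' @export
plot_tilt_free_energy <- function(fit) {
  stopifnot(inherits(fit, "tilt_fit"))
  d <- fit$distribution[is.finite(fit$distribution$f), ]
  aa <- seq(min(d$alpha), max(d$alpha), length.out = 200)
  fmin <- min(d$f)
  curve <- tibble::tibble(alpha = aa,
                          f = fmin + fit$chi / 2 * (aa - fit$alpha0)^2)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$alpha, y = .data$f)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "red") +
    ggplot2::labs(x = "tilt angle (rad)", y = "F (kBT)",
                  title = "Tilt free energy (Boltzmann inversion)",
                  subtitle = sprintf("chi = %.2f kBT/rad^2", fit$chi))
}
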