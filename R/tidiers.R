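#' Broom-style tidiers for fitted objects
#'
#' `tidy()` returns one row per estimated term; `glance()` a one-row model
#' summary.
#'
#' @name tidiers
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.ka_estimate <- function(x, ...) {
  tibble::tibble(term = "KA", estimate = x$KA, std.error = x$se,
                 unit = "mN/m")
}

#' @exportS3Method generics::glance
glance.ka_estimate <- function(x, ...) {
  tibble::tibble(mean_area = x$mean_area, variance = x$variance, N = x$N,
                 temperature = x$temperature, n_frames = x$n_frames,
                 n_blocks = x$n_blocks)
}

#' @exportS3Method generics::tidy
tidy.tilt_fit <- function(x, ...) {
  tibble::tibble(term = c("chi", "alpha0"),
                 estimate = c(x$chi, x$alpha0),
                 std.error = c(x$se, NA_real_),
                 unit = c("kBT/rad^2", "rad"))
}

#' @exportS3Method generics::glance
glance.tilt_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, n_fit_points = x$n_fit_points,
                 n_samples = x$n_samples, window_kBT = x$window_kBT)
}

#' @exportS3Method generics::tidy
tidy.spectrum_fit <- function(x, ...) {
  tibble::tibble(term = c("KC", "chi_s"),
                 estimate = c(x$kc, x$chi_s),
                 std.error = c(x$kc_se, x$chi_s_se),
                 unit = c("kBT", "kBT/nm^2"))
}

#' @exportS3Method generics::glance
glance.spectrum_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, n_modes = x$n_modes,
                 n_frames = x$n_frames, q_cut = x$q_cut)
}

#' @exportS3Method generics::tidy
tidy.permeability_result <- function(x, ...) {
  tibble::tibble(term = c("P", "R_total"),
                 estimate = c(x$P, x$R_total),
                 std.error = c(x$se, NA_real_),
                 unit = c("cm/s", "s/cm"))
}

#' @exportS3Method generics::glance
glance.permeability_result <- function(x, ...) {
  tibble::tibble(bounds_lo = x$bounds[1], bounds_hi = x$bounds[2],
                 z_max_resistance = x$z_max_resistance)
}

#' @exportS3Method generics::tidy
tidy.diffusivity_estimate <- function(x, ...) {
  tibble::tibble(term = "D", estimate = x$D_cm2s, std.error = NA_real_,
                 unit = "cm^2/s")
}
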