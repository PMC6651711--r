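#' Inhomogeneous solubility-diffusivity permeation pipeline
#'
#' Free energy of permeation by thermodynamic integration of mean
#' constraint forces, local diffusivity from the force autocorrelation
#' function, the partition coefficient `K(z) = exp(-dG/kBT)`, the local
#' resistance `exp(dG/kBT)/D(z)`, and the overall permeability
#' `P = 1 / integral R_local dz`.
#'
#' @name permeation
NULL

as_force_window_list <- function(windows) {
  if (inherits(windows, "force_window")) return(list(windows))
  stopifnot(is.list(windows), length(windows) >= 1)
  lapply(windows, function(w) {
    stopifnot(inherits(w, "force_window"))
    w
  })
}

#' Construct a constraint-force window
#'
#' @param z constraint distance from the membrane center, nm
#' @param forces force time series on the permeant along z, kJ/mol/nm
#'   (positive = toward bulk)
#' @param dt sampling interval, ps
#' @param temperature K
#' @param replicate replicate id (independent starting configurations)
#' @return an object of class `force_window`
#' @export
force_window <- function(z, forces, dt, temperature = 298, replicate = 1) {
  if (length(forces) < 2) stop("force series needs at least 2 samples", call. = FALSE)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  structure(list(z = z, forces = as.numeric(forces), dt = dt,
                 temperature = temperature, replicate = replicate),
            class = "force_window")
}

window_mean <- function(w, burn_in) {
  f <- w$forces
  drop <- floor(length(f) * burn_in)
  if (drop > 0) f <- f[-seq_len(drop)]
  f
}

#' Permeation free energy by thermodynamic integration
#'
#' Pools replicate windows at equal z (grand mean force; between-replicate
#' scatter sets the error bar), then integrates the mean force inward from
#' the outermost window by the trapezoid rule on the window grid:
#' `dG(z) = integral_z^z_bulk <f> dz'` with `dG(z_bulk) = 0`, so a mean
#' force pushing the permeant toward bulk yields a positive free energy
#' inside the membrane.
#'
#' @param windows a `force_windows` collection (see
#'   [generate_force_windows()]) or a list of [force_window()] objects
#' @param burn_in fraction of each series discarded as equilibration
#' @return a tibble of class `free_energy_profile`: `z` (nm), `mean_force`
#'   (kJ/mol/nm), `dG` (kJ/mol), `se`, `n_replicates`; attribute
#'   `temperature`
#' @export
free_energy_TI <- function(windows, burn_in = 0.1) {
  ws <- as_force_window_list(windows)
  if (length(unique(vapply(ws, function(w) w$z, numeric(1)))) < 2) {
    stop("thermodynamic integration needs windows at >= 2 distinct z",
         call. = FALSE)
  }
  per <- purrr::map_dfr(ws, function(w) {
    f <- window_mean(w, burn_in)
    tibble::tibble(z = w$z, fmean = mean(f),
                   fvar = stats::var(f), n = length(f),
                   temperature = w$temperature)
  })
  pooled <- per |>
    dplyr::group_by(.data$z) |>
    dplyr::summarise(
      mean_force = mean(.data$fmean),
      se_force = if (dplyr::n() > 1) {
        stats::sd(.data$fmean) / sqrt(dplyr::n())
      } else sqrt(.data$fvar[1] / .data$n[1]),
      n_replicates = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$z)
  K <- nrow(pooled)
  z <- pooled$z; f <- pooled$mean_force
  dz <- diff(z)
  # trapezoid from z_k up to z_bulk = z_K
  seg <- 0.5 * (f[-K] + f[-1]) * dz
  dG <- c(rev(cumsum(rev(seg))), 0)
  # error propagation through the trapezoid weights
  wts <- numeric(K)
  varG <- vapply(seq_len(K), function(k) {
    if (k == K) return(0)
    w <- numeric(K)
    for (j in k:(K - 1)) {
      w[j] <- w[j] + 0.5 * dz[j]
      w[j + 1] <- w[j + 1] + 0.5 * dz[j]
    }
    sum(w^2 * pooled$se_force^2)
  }, numeric(1))
  out <- tibble::tibble(z = z, mean_force = f, dG = dG, se = sqrt(varG),
                        n_replicates = pooled$n_replicates)
  attr(out, "temperature") <- per$temperature[1]
  class(out) <- c("free_energy_profile", class(out))
  out
}

#' Partition coefficient profile
#'
#' `K(z) = exp(-dG(z)/kBT)`; equals 1 in bulk where `dG = 0`.
#'
#' @param dg a `free_energy_profile` (or tibble with `z`, `dG` in kJ/mol)
#' @param temperature K (defaults to the profile's attribute)
#' @return a tibble of class `partition_profile`: `z`, `K`
#' @export
partition_profile <- function(dg, temperature = NULL) {
  temperature <- temperature %||% attr(dg, "temperature") %||% 298
  if (temperature <= 0) stop("temperature must be positive", call. = FALSE)
  out <- tibble::tibble(z = dg$z, K = exp(-dg$dG / kBT_kJmol(temperature)))
  class(out) <- c("partition_profile", class(out))
  out
}

#' Force autocorrelation function
#'
#' Autocovariance of the mean-subtracted series at lags `0..max_lag`,
#' unbiased normalization (`1/(n-k)` pairs at lag k), computed via FFT with
#' zero padding.
#'
#' @param f numeric series
#' @param max_lag largest lag (default `length(f) - 1`)
#' @return numeric vector of length `max_lag + 1`
#' @export
force_acf <- function(f, max_lag = length(f) - 1) {
  n <- length(f)
  x <- f - mean(f)
  m <- 2^ceiling(log2(2 * n))
  X <- stats::fft(c(x, rep(0, m - n)))
  s <- Re(stats::fft(X * Conj(X), inverse = TRUE)) / m
  s[seq_len(max_lag + 1)] / (n - 0:max_lag)
}

#' Local diffusivity from the force autocorrelation function
#'
#' `D(z) = (RT)^2 / integral_0^tc <dF(t) dF(0)> dt`, where the cutoff `tc`
#' is the first plateau of the running (trapezoid) integral, detected as
#' its first local maximum after smoothing over 5 points. The search is
#' limited to the first third of the series; a running integral that never
#' plateaus there raises an error with diagnostics.
#'
#' @param window a [force_window()]
#' @param burn_in fraction discarded as equilibration
#' @param smooth points in the moving average used for plateau detection
#' @return an object of class `diffusivity_estimate`: `z`, `D_nm2ps`,
#'   `D_cm2s`, `acf_integral` ((kJ/mol/nm)^2 ps), `tc` (ps),
#'   `correlation_time` (ps, integral timescale)
#' @export
local_diffusivity <- function(window, burn_in = 0.1, smooth = 5) {
  stopifnot(inherits(window, "force_window"))
  f <- window_mean(window, burn_in)
  n <- length(f)
  max_lag <- floor(n / 3)
  ac <- force_acf(f, max_lag)
  dt <- window$dt
  run <- (cumsum(ac) - 0.5 * ac - 0.5 * ac[1]) * dt  # trapezoid running integral
  k <- max(1L, floor(smooth / 2))
  sm <- stats::filter(run, rep(1 / (2 * k + 1), 2 * k + 1), sides = 2)
  sm[is.na(sm)] <- run[is.na(sm)]
  d <- diff(sm)
  turn <- which(d <= 0)
  turn <- turn[turn > k]  # ignore the smoothing edge at lag 0
  if (length(turn) == 0) {
    stop(sprintf(paste0(
      "force ACF shows no plateau within the first third of the series ",
      "(n = %d, max lag = %.1f ps, running integral still rising: %.4g -> %.4g); ",
      "series too short or non-stationary"),
      n, max_lag * dt, run[max(1, length(run) %/% 2)], run[length(run)]),
      call. = FALSE)
  }
  ic <- turn[1]
  I <- run[ic]
  if (I <= 0) stop("non-positive ACF integral at the detected cutoff", call. = FALSE)
  RT <- kBT_kJmol(window$temperature)
  D <- RT^2 / I
  structure(list(z = window$z, D_nm2ps = D, D_cm2s = diffusivity_to_cm2s(D),
                 acf_integral = I, tc = ic * dt,
                 correlation_time = I / ac[1]),
            class = "diffusivity_estimate")
}

#' @export
print.diffusivity_estimate <- function(x, ...) {
  cat(sprintf("D(z = %.2f nm) = %.3g cm^2/s (ACF cutoff %.1f ps, tau ~ %.2f ps)\n",
              x$z, x$D_cm2s, x$tc, x$correlation_time))
  invisible(x)
}

#' Local diffusivity profile over a set of force windows
#'
#' Replicates at equal z are estimated independently and pooled; the
#' between-replicate scatter gives the error bar.
#'
#' @param windows a `force_windows` collection or list of [force_window()]s
#' @param ... passed to [local_diffusivity()]
#' @return a tibble of class `diffusivity_profile`: `z`, `D` (cm^2/s),
#'   `D_nm2ps`, `se` (cm^2/s), `tc` (ps), `n_replicates`
#' @export
diffusivity_profile <- function(windows, ...) {
  ws <- as_force_window_list(windows)
  per <- purrr::map_dfr(ws, function(w) {
    est <- local_diffusivity(w, ...)
    tibble::tibble(z = est$z, D_nm2ps = est$D_nm2ps, tc = est$tc)
  })
  out <- per |>
    dplyr::group_by(.data$z) |>
    dplyr::summarise(
      D = diffusivity_to_cm2s(mean(.data$D_nm2ps)),
      D_nm2ps = mean(.data$D_nm2ps),
      se = if (dplyr::n() > 1) {
        diffusivity_to_cm2s(stats::sd(.data$D_nm2ps) / sqrt(dplyr::n()))
      } else NA_real_,
      tc = mean(.data$tc), n_replicates = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$z)
  class(out) <- c("diffusivity_profile", class(out))
  out
}

#' Local permeation resistance profile
#'
#' `R_local(z) = exp(dG(z)/kBT) / D(z)`, pointwise on the free-energy grid;
#' a diffusivity profile on a different grid is linearly interpolated onto
#' it (logged). Uncertainty by first-order propagation of the free-energy
#' and diffusivity errors.
#'
#' @param dg a `free_energy_profile`
#' @param d a `diffusivity_profile` (or tibble with `z` and `D_nm2ps`)
#' @param temperature K (defaults to the free-energy profile attribute)
#' @return a tibble of class `resistance_profile`: `z` (nm), `r_local`
#'   (s/cm^2), `r_local_psnm2` (internal units), `se` (s/cm^2)
#' @export
resistance_profile <- function(dg, d, temperature = NULL) {
  temperature <- temperature %||% attr(dg, "temperature") %||% 298
  kT <- kBT_kJmol(temperature)
  Dz <- d$z; Dv <- d$D_nm2ps
  if (any(Dv <= 0)) stop("diffusivity must be positive everywhere", call. = FALSE)
  Dse <- if ("se" %in% names(d) && any(is.finite(d$se))) {
    ifelse(is.finite(d$se), d$se / .nm2ps_to_cm2s, 0)
  } else rep(0, length(Dv))
  if (!isTRUE(all.equal(Dz, dg$z))) {
    message("resistance_profile: interpolating D(z) onto the free-energy grid")
    Dv <- stats::approx(Dz, Dv, xout = dg$z, rule = 2)$y
    Dse <- stats::approx(Dz, Dse, xout = dg$z, rule = 2)$y
  }
  r <- exp(dg$dG / kT) / Dv  # ps/nm^2
  se_dg <- if ("se" %in% names(dg)) ifelse(is.finite(dg$se), dg$se, 0) else 0
  rel <- sqrt((se_dg / kT)^2 + (Dse / Dv)^2)
  # r in ps/nm^2 -> s/cm^2: 1 ps/nm^2 = 1e-12 s / 1e-14 cm^2 = 100 s/cm^2
  out <- tibble::tibble(z = dg$z, r_local = r * 100, r_local_psnm2 = r,
                        se = r * rel * 100)
  class(out) <- c("resistance_profile", class(out))
  attr(out, "temperature") <- temperature
  out
}

#' Overall permeability from the resistance profile
#'
#' Integrates the local resistance over the permeation path by the
#' trapezoid rule and inverts it: `P = 1/R_total`. A one-sided profile on
#' `z >= 0` is mirrored across the bilayer center (`mirror = TRUE`, the
#' default) so the integral covers the full membrane.
#'
#' @param r a `resistance_profile`
#' @param bounds integration bounds in nm, e.g. `c(-2.8, 2.8)`; default the
#'   full (mirrored) profile support
#' @param mirror reflect a one-sided profile about z = 0
#' @return an object of class `permeability_result`: `P` (cm/s), `se`,
#'   `R_total` (s/cm), `bounds`, `z_max_resistance` (nm)
#' @export
permeability <- function(r, bounds = NULL, mirror = TRUE) {
  stopifnot(inherits(r, "resistance_profile") ||
              all(c("z", "r_local_psnm2") %in% names(r)))
  z <- r$z; rv <- r$r_local_psnm2
  se <- if ("se" %in% names(r)) r$se / 100 else rep(0, length(z))  # back to ps/nm^2
  if (mirror && min(z) >= 0) {
    neg <- rev(which(z > 0))
    z <- c(-z[neg], z)
    rv <- c(rv[neg], rv)
    se <- c(se[neg], se)
  }
  if (is.null(bounds)) bounds <- range(z)
  if (bounds[1] < min(z) - 1e-9 || bounds[2] > max(z) + 1e-9) {
    stop(sprintf("bounds [%g, %g] outside profile support [%g, %g]",
                 bounds[1], bounds[2], min(z), max(z)), call. = FALSE)
  }
  keep <- z >= bounds[1] - 1e-9 & z <= bounds[2] + 1e-9
  z <- z[keep]; rv <- rv[keep]; se <- se[keep]
  K <- length(z)
  if (K < 2) stop("need at least 2 points inside bounds", call. = FALSE)
  dz <- diff(z)
  R_psnm <- sum(0.5 * (rv[-K] + rv[-1]) * dz)
  wts <- c(0.5 * dz[1], 0.5 * (dz[-1] + dz[-(K - 1)]), 0.5 * dz[K - 1])
  if (K == 2) wts <- c(0.5 * dz[1], 0.5 * dz[1])
  R_se <- sqrt(sum(wts^2 * se^2))
  R_scm <- R_psnm * .psnm_to_scm
  P <- (1 / R_psnm) * .nmps_to_cms
  structure(list(P = P, se = P * R_se / R_psnm, R_total = R_scm,
                 bounds = bounds, z_max_resistance = z[which.max(rv)]),
            class = "permeability_result")
}

#' @export
print.permeability_result <- function(x, ...) {
  cat(sprintf(
    "P = %.3g cm/s (R_total = %.3g s/cm, bounds [%.2f, %.2f] nm, peak resistance at z = %.2f nm)\n",
    x$P, x$R_total, x$bounds[1], x$bounds[2], x$z_max_resistance))
  invisible(x)
}

#' Run the full solubility-diffusivity pipeline on force windows
#'
#' Thermodynamic integration, local diffusivities, local resistance and the
#' overall permeability in one pass.
#'
#' @param windows a `force_windows` collection or list of [force_window()]s
#' @param burn_in equilibration fraction discarded from every series
#' @param bounds integration bounds for [permeability()]
#' @param mirror see [permeability()]
#' @return a list with `free_energy`, `diffusivity`, `resistance`,
#'   `permeability`
#' @export
permeation_pipeline <- function(windows, burn_in = 0.1, bounds = NULL,
                                mirror = TRUE) {
  dg <- free_energy_TI(windows, burn_in = burn_in)
  dp <- diffusivity_profile(windows, burn_in = burn_in)
  rp <- resistance_profile(dg, dp)
  pm <- permeability(rp, bounds = bounds, mirror = mirror)
  list(free_energy = dg, diffusivity = dp, resistance = rp, permeability = pm)
}
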