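noiseless_windows <- function(z, f_fun, temperature = 298) {
  lapply(z, function(zi) {
    force_window(zi, rep(f_fun(zi), 10), dt = 1, temperature = temperature)
  })
}

test_that("thermodynamic integration: flat, constant-force and linearity identities", {
  z <- seq(0, 2.8, 0.2)
  dg0 <- free_energy_TI(noiseless_windows(z, function(z) 0), burn_in = 0)
  expect_true(all(dg0$dG == 0))

  # constant force c: |dG(0)| = 2.8 * c exactly (rectangle integral)
  dgc <- free_energy_TI(noiseless_windows(z, function(z) 3), burn_in = 0)
  expect_equal(dgc$dG[dgc$z == 0], 2.8 * 3, tolerance = 1e-12)
  expect_equal(dgc$dG[dgc$z == 2.8], 0)

  # exact linearity in the forces
  f <- function(z) sin(z) + 0.3
  a <- free_energy_TI(noiseless_windows(z, f), burn_in = 0)
  b <- free_energy_TI(noiseless_windows(z, function(z) 2.5 * f(z)), burn_in = 0)
  expect_equal(b$dG, 2.5 * a$dG, tolerance = 1e-12)

  expect_error(free_energy_TI(noiseless_windows(1.0, function(z) 0)),
               "2 distinct z")
})

test_that("TI equals the trapezoid oracle and recovers a 30 kJ/mol barrier", {
  z <- seq(0, 2.8, 0.2)
  fr <- gaussian_barrier_force(30, 1.0, 0.4)
  dg <- free_energy_TI(noiseless_windows(z, fr), burn_in = 0)
  # frozen oracle: composite trapezoid of the exact forces, integrated inward
  fv <- fr(z); K <- length(z)
  seg <- 0.5 * (fv[-K] + fv[-1]) * diff(z)
  oracle <- c(rev(cumsum(rev(seg))), 0)
  expect_equal(dg$dG, oracle, tolerance = 1e-12)
  # the peak sits within the analytic composite-trapezoid error of 30 kJ/mol
  eps <- 0.2^2 / 12 * 30 / 0.4^2 * 1.2  # bound with 20% headroom for G'''' terms
  expect_lt(abs(max(dg$dG) - 30), eps)
})

test_that("replicate windows pool into a grand mean with between-replicate errors", {
  mk <- function(z, val) force_window(z, rep(val, 50), dt = 1)
  ws <- list(mk(0, 1), mk(0, 3), mk(1, 0), mk(1, 0))
  dg <- free_energy_TI(ws, burn_in = 0)
  expect_equal(dg$mean_force[dg$z == 0], 2)  # grand mean of 1 and 3
  expect_equal(dg$n_replicates, c(2L, 2L))
  expect_true(dg$se[dg$z == 0] > 0)
})

test_that("partition coefficient follows the Boltzmann closed forms", {
  kT <- kBT_kJmol(298)
  dg <- tibble::tibble(z = c(0, 1, 2), dG = c(0, kT * log(2), 30))
  K <- partition_profile(dg, temperature = 298)
  expect_equal(K$K[1], 1)
  expect_equal(K$K[2], 0.5, tolerance = 1e-12)
  expect_equal(K$K[3], exp(-30 / (0.0083144621 * 298)), tolerance = 1e-12)
})

test_that("FFT autocorrelation equals the direct quadratic-time oracle", {
  set.seed(33)
  for (n in c(64, 257, 512)) {
    f <- as.numeric(arima.sim(list(ar = 0.8), n))
    expect_equal(force_acf(f, n - 1), direct_acf(f, n - 1), tolerance = 1e-10)
  }
})

test_that("force-ACF diffusivity recovers the OU ground truth and its scaling", {
  fs <- force_spec(c(0, 2.8), 0, force_variance = 1e4, correlation_time = 1,
                   dt = 0.1, n_steps = 1e5, temperature = 298, seed = 41)
  w <- generate_force_windows(fs)[[1]]
  est <- local_diffusivity(w)
  D_true <- (0.0083144621 * 298)^2 / (1e4 * 1)
  expect_lt(abs(est$D_nm2ps - D_true) / D_true, 0.15)
  expect_equal(est$D_cm2s, est$D_nm2ps * 1e-2, tolerance = 1e-12)

  # doubling the force variance halves D
  fs2 <- force_spec(c(0, 2.8), 0, 2e4, 1, 0.1, 1e5, temperature = 298,
                    seed = 41)
  est2 <- local_diffusivity(generate_force_windows(fs2)[[1]])
  expect_equal(est2$D_nm2ps / est$D_nm2ps, 0.5, tolerance = 0.1)
})

test_that("a non-decaying force ACF raises an informative error", {
  # a deterministic ramp: its autocovariance stays positive over the whole
  # analysable lag range, so the running integral never plateaus
  w <- force_window(1.0, seq(0, 20, length.out = 2000), dt = 0.1)
  expect_error(local_diffusivity(w), "no plateau")
})

test_that("resistance profile: closed forms and cross-grid interpolation", {
  kT <- kBT_kJmol(298)
  dg <- structure(tibble::tibble(z = c(0, 1, 2), dG = c(0, 0, 0),
                                 se = c(0, 0, 0)),
                  class = c("free_energy_profile", class(tibble::tibble())),
                  temperature = 298)
  d <- tibble::tibble(z = c(0, 1, 2), D_nm2ps = 0.02)
  r <- resistance_profile(dg, d)
  expect_equal(r$r_local_psnm2, rep(1 / 0.02, 3))

  dg$dG <- rep(kT, 3)
  r2 <- resistance_profile(dg, d)
  expect_equal(r2$r_local_psnm2, rep(exp(1) / 0.02, 3), tolerance = 1e-12)

  # offset diffusivity grid: hand-worked linear interpolation on 3 points
  d_off <- tibble::tibble(z = c(0.1, 1.1, 2.1), D_nm2ps = c(0.02, 0.04, 0.06))
  dg$dG <- c(0, 0, 0)
  expect_message(r3 <- resistance_profile(dg, d_off), "interpolating")
  # at z = 1: D = 0.02 + (1 - 0.1)/(1.1 - 0.1) * (0.04 - 0.02) = 0.038
  expect_equal(r3$r_local_psnm2[2], 1 / 0.038, tolerance = 1e-12)
  # z = 0 lies outside the D grid: nearest value is carried (rule = 2)
  expect_equal(r3$r_local_psnm2[1], 1 / 0.02, tolerance = 1e-12)

  d_bad <- tibble::tibble(z = c(0, 1, 2), D_nm2ps = c(0.02, -1, 0.02))
  expect_error(resistance_profile(dg, d_bad), "positive")
})

test_that("permeability closed forms: homogeneous membrane and square barrier", {
  kT <- kBT_kJmol(298)
  D0 <- 0.03  # nm^2/ps
  h <- 5.6    # nm, mirrored from a 2.8 nm half profile
  z <- seq(0, 2.8, 0.2)
  r <- tibble::tibble(z = z, r_local_psnm2 = 1 / D0,
                      r_local = 100 / D0, se = 0)
  class(r) <- c("resistance_profile", class(r))
  p <- permeability(r)
  expect_equal(p$P, D0 / h * 1e5, tolerance = 1e-12)  # P = D/h in cm/s

  # square barrier dG = G0 on [0.8, 1.8]: P = D/(w e^{G0/kT} + (h - w))
  G0 <- 5; zf <- seq(0, 2.8, 0.001)
  dG <- ifelse(zf >= 0.8 & zf <= 1.8, G0, 0)
  rf <- tibble::tibble(z = zf, r_local_psnm2 = exp(dG / kT) / D0,
                       r_local = 100 * exp(dG / kT) / D0, se = 0)
  class(rf) <- c("resistance_profile", class(rf))
  pf <- permeability(rf)
  w_b <- 2  # mirrored barrier width, nm
  P_closed <- D0 / (w_b * exp(G0 / kT) + (h - w_b)) * 1e5
  expect_lt(abs(pf$P - P_closed) / P_closed, 0.005)

  # doubling the local resistance everywhere halves P
  r2 <- r; r2$r_local_psnm2 <- 2 * r2$r_local_psnm2
  expect_equal(permeability(r2)$P, p$P / 2, tolerance = 1e-12)

  expect_error(permeability(r, bounds = c(-5, 5)), "outside")
})

test_that("resistance is monotone in the free energy (pointwise)", {
  kT <- kBT_kJmol(298)
  d <- tibble::tibble(z = seq(0, 2, 0.5), D_nm2ps = 0.02)
  base <- tibble::tibble(z = seq(0, 2, 0.5), dG = c(0, 1, 3, 2, 0), se = 0)
  up <- base; up$dG <- base$dG + c(0, 0.5, 1, 0.2, 0)
  r1 <- resistance_profile(structure(base, temperature = 298), d)
  r2 <- resistance_profile(structure(up, temperature = 298), d)
  expect_true(all(r2$r_local_psnm2 >= r1$r_local_psnm2))
})

test_that("end-to-end pipeline recovers the analytic permeability on a resolved barrier", {
  # a 10 kJ/mol, sigma = 0.5 nm barrier is resolved by the 0.2 nm window
  # grid, so the recovery isolates estimator error from quadrature bias
  spec <- force_spec(seq(0, 2.8, 0.2), gaussian_barrier_force(10, 1.0, 0.5),
                     force_variance = 400, correlation_time = 0.5, dt = 0.05,
                     n_steps = 10000, temperature = 298, n_replicates = 10,
                     seed = 55)
  ws <- generate_force_windows(spec)
  pipe <- permeation_pipeline(ws)
  gt <- attr(ws, "ground_truth")
  P_true <- analytic_permeability(gaussian_dG(10, 1.0, 0.5), gt$D, 2.8)
  expect_lt(abs(pipe$permeability$P - P_true) / P_true, 0.20)
  expect_equal(pipe$permeability$P, 1 / pipe$permeability$R_total,
               tolerance = 1e-9)
  expect_equal(abs(pipe$permeability$z_max_resistance), 1.0, tolerance = 0.21)
})
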