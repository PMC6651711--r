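test_that("every generator is bitwise-reproducible under a fixed seed", {
  s <- chain_spec(20, 12, 0.4, 0.2, seed = 99)
  a <- generate_chain_frames(s); b <- generate_chain_frames(s)
  expect_identical(a$frames$coords, b$frames$coords)

  sp <- surface_spec(20, 20, 16, 15, 2, n_frames = 3, seed = 5)
  expect_identical(generate_height_frames(sp)$fields,
                   generate_height_frames(sp)$fields)

  expect_identical(generate_area_series(0.6, 500, n_frames = 50, seed = 3),
                   generate_area_series(0.6, 500, n_frames = 50, seed = 3))

  fs <- force_spec(c(0, 1), 2, 100, 1, 0.1, 200, seed = 7)
  wa <- generate_force_windows(fs); wb <- generate_force_windows(fs)
  expect_identical(wa[[1]]$forces, wb[[1]]$forces)

  # and the generator must not disturb the caller's RNG stream
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(generate_chain_frames(s)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("generator specs reject invalid parameters", {
  expect_error(chain_spec(10, 3, 0.4, 0.2), "n_carbons")
  expect_error(chain_spec(10, 12, 1.4, 0.2), "order_param_target")
  expect_error(chain_spec(10, 12, 0.4, 1.2), "gauche_prob")
  expect_error(surface_spec(20, 20, 4, 15), "n_grid")
  expect_error(surface_spec(20, 20, 16, -1), "KC_true")
  expect_error(generate_area_series(0.6, -5), "KA_true")
  expect_error(force_spec(c(0, 1), 0, 100, correlation_time = 1, dt = 2,
                          n_steps = 100), "dt")
  expect_error(force_spec(c(1, 0.5), 0, 100, 1, 0.1, 100), "increasing")
})

test_that("chain fixture realizes its Bernoulli gauche sequence and Watson order", {
  # ~1e4 dihedrals: realized fraction within 3 binomial SEs of the target
  s <- chain_spec(770, 16, 0.45, 0.3, seed = 21)
  ch <- generate_chain_frames(s)
  gt <- attr(ch, "ground_truth")
  n_dih <- 770 * 13
  expect_lt(abs(gt$gauche_fraction_realized - 0.3),
            3 * sqrt(0.3 * 0.7 / n_dih))
  # the built geometry reproduces the drawn gauche flags exactly
  g <- gauche_fraction(ch$frames, ch$topology)
  expect_equal(stats::weighted.mean(g$gauche, g$n_samples),
               gt$gauche_fraction_realized, tolerance = 1e-12)
})

test_that("surface generator follows the Helfrich spectrum law mode by mode", {
  sp <- surface_spec(20, 20, 16, KC_true = 10, chi_true = 0,
                     n_frames = 600, seed = 8)
  hf <- generate_height_frames(sp)
  spec <- height_spectrum(hf)
  law <- 1 / (10 * spec$q^4)
  # per-shell relative error ~ 1/sqrt(n_frames * n_modes); allow 5 sigma
  rel <- abs(spec$h2 - law) / law
  expect_true(all(rel < 5 / sqrt(600 * spec$n_modes)))
  # pure q^-4: log-log slope of the spectrum is -4
  fitc <- stats::coef(stats::lm(log(h2) ~ log(q), data = spec))
  expect_equal(unname(fitc[2]), -4, tolerance = 0.05)
})

test_that("single-frame ensembles carry the no-averaging (infinite variance) flag", {
  sp <- surface_spec(20, 20, 16, 10, n_frames = 1, seed = 2)
  spec <- height_spectrum(generate_height_frames(sp))
  expect_true(all(is.infinite(spec$se)))
})

test_that("area series has the variance the compressibility law dictates", {
  kT <- kBT_kJmol(298)
  ka_kJ <- 700 / ka_to_mNm(1)
  v_expected <- kT * 0.6 / (64 * ka_kJ)
  a <- generate_area_series(0.6, 700, N = 64, n_frames = 20000, seed = 4)
  expect_equal(attr(a, "ground_truth")$variance, v_expected, tolerance = 1e-12)
  # sample variance concentrates around the target: sd(var) ~ var*sqrt(2/n)
  expect_lt(abs(stats::var(a$area_per_mol) - v_expected),
            5 * v_expected * sqrt(2 / 20000))
})

test_that("the exact OU update has the stationary statistics it advertises", {
  fs <- force_spec(c(0, 1), mean_force_profile = 5, force_variance = 50,
                   correlation_time = 2, dt = 0.4, n_steps = 50000, seed = 31)
  w <- generate_force_windows(fs)[[1]]
  f <- w$forces
  expect_equal(mean(f), 5, tolerance = 0.15)
  expect_equal(stats::var(f), 50, tolerance = 0.05 * 50 * 5)
  # lag-1 autocorrelation = exp(-dt/tau) even at coarse dt (exact update)
  r1 <- stats::cor(f[-1], f[-length(f)])
  expect_equal(r1, exp(-0.4 / 2), tolerance = 0.02)
})

test_that("force windows carry analytic free-energy and diffusivity ground truth", {
  fs <- force_spec(seq(0, 2, 0.5), gaussian_barrier_force(10, 1, 0.4),
                   force_variance = 100, correlation_time = 1, dt = 0.1,
                   n_steps = 100, temperature = 298, seed = 2)
  ws <- generate_force_windows(fs)
  gt <- attr(ws, "ground_truth")
  G <- gaussian_dG(10, 1, 0.4)
  expect_equal(gt$dG$dG, G(gt$dG$z) - G(2), tolerance = 1e-7)
  RT <- kBT_kJmol(298)
  expect_equal(gt$D, RT^2 / (100 * 1), tolerance = 1e-12)
  # flat landscape: zero mean force everywhere -> dG identically 0
  fs0 <- force_spec(seq(0, 2, 0.5), 0, 100, 1, 0.1, 100, seed = 2)
  expect_true(all(attr(generate_force_windows(fs0), "ground_truth")$dG$dG == 0))
})
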