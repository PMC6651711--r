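test_that("area compressibility recovers ground truth and obeys its scaling laws", {
  a <- generate_area_series(0.62, 700, N = 64, n_frames = 10000, seed = 12)
  ka <- area_compressibility(a)
  expect_lt(abs(ka$KA - 700) / 700, 0.05)

  # invariant under frame reordering
  perm <- a[sample(nrow(a)), ]
  attributes(perm)[c("N", "temperature")] <- attributes(a)[c("N", "temperature")]
  expect_equal(area_compressibility(perm)$KA, ka$KA, tolerance = 1e-12)

  # linear in temperature at fixed series
  expect_equal(area_compressibility(a, temperature = 596)$KA, 2 * ka$KA,
               tolerance = 1e-10)

  # doubling the variance at fixed mean halves the modulus
  doubled <- tibble::tibble(
    area_per_mol = mean(a$area_per_mol) +
      sqrt(2) * (a$area_per_mol - mean(a$area_per_mol)))
  ka2 <- area_compressibility(doubled, temperature = 298, N = 64)
  expect_equal(ka2$KA, ka$KA / 2, tolerance = 1e-10)
})

test_that("area compressibility flags rigid and under-sampled series", {
  rigid <- tibble::tibble(area_per_mol = rep(0.6, 500))
  expect_true(is.infinite(area_compressibility(rigid, N = 64)$KA))
  short <- tibble::tibble(area_per_mol = c(0.60, 0.61))
  expect_warning(area_compressibility(short, N = 64), "unreliable")
})

test_that("tilt free energy is flat for hemisphere-uniform chains (Jacobian check)", {
  ang <- sample_tilt_angles(40000, chi = 0, seed = 6)
  fit <- tilt_modulus(ang)
  expect_lt(abs(fit$chi), 0.5)
})

test_that("tilt modulus recovers the generator curvature and rejects degenerate input", {
  ang <- sample_tilt_angles(20000, chi = 13, alpha0 = 0.3, seed = 9)
  fit <- tilt_modulus(ang)
  expect_lt(abs(fit$chi - 13) / 13, 0.10)
  expect_equal(fit$alpha0, 0.3, tolerance = 0.05)
  expect_error(tilt_modulus(rep(0.4, 5000)), "degenerate")
})

test_that("tilt angles from chain geometry feed the modulus estimator", {
  ch <- generate_chain_frames(chain_spec(60, 10, 0.45, 0, seed = 4))
  ta <- tilt_angles(ch$frames, ch$topology)
  expect_true(all(is.finite(ta$alpha)))
  expect_true(all(ta$alpha >= 0 & ta$alpha <= pi))
})

test_that("height-field fit: constant, in-basis, noisy and degenerate cases", {
  set.seed(10)
  pts <- cbind(runif(64, 0, 10), runif(64, 0, 10), 0)
  flat <- fit_height_field(cbind(pts[, 1:2], 2.5), 10, 10)
  b00 <- flat$coefficients$value[flat$coefficients$m == 0 &
                                   flat$coefficients$n == 0 &
                                   flat$coefficients$trig == "cos"]
  expect_equal(b00, 2.5, tolerance = 1e-10)
  expect_lt(max(abs(flat$coefficients$value[-which(
    flat$coefficients$m == 0 & flat$coefficients$n == 0 &
      flat$coefficients$trig == "cos")])), 1e-10)
  expect_lt(flat$residual_rms, 1e-10)

  z <- 0.8 * sin(2 * pi * (pts[, 1] / 10 + pts[, 2] / 10))
  one <- fit_height_field(cbind(pts[, 1:2], z), 10, 10)
  a11 <- one$coefficients$value[one$coefficients$m == 1 &
                                  one$coefficients$n == 1 &
                                  one$coefficients$trig == "sin"]
  expect_equal(a11, 0.8, tolerance = 1e-10)
  expect_lt(one$residual_rms, 1e-10)

  noisy <- fit_height_field(cbind(pts[, 1:2], rnorm(64, 0, 0.05)), 10, 10)
  expect_equal(noisy$residual_rms, 0.05, tolerance = 0.4)

  line <- cbind(seq(0, 10, length.out = 30), 5, 1)  # collinear points
  expect_error(fit_height_field(line, 10, 10), "rank-deficient")
})

test_that("spectrum estimator equals the direct-summation Fourier oracle", {
  sp <- surface_spec(12, 12, 8, 5, 1, n_frames = 1, seed = 13)
  h <- generate_height_frames(sp)$fields[[1]]
  spec <- height_spectrum(list(h), Lx = 12, Ly = 12)
  # rebuild every shell mean from the O(N^4) direct double-sum transform
  N <- 8
  qs <- c(); pw <- c()
  for (m in 0:(N - 1)) for (n in 0:(N - 1)) {
    mm <- if (m > N / 2) m - N else m
    nn <- if (n > N / 2) n - N else n
    if ((mm == 0 && nn == 0) || abs(mm) > 3 || abs(nn) > 3) next
    qs <- c(qs, 2 * pi * sqrt((mm / 12)^2 + (nn / 12)^2))
    pw <- c(pw, direct_mode_power(h, m, n, 12, 12))
  }
  oracle <- vapply(spec$q, function(qq) mean(pw[abs(qs - qq) < 1e-9]),
                   numeric(1))
  expect_equal(spec$h2, oracle, tolerance = 1e-10)
})

test_that("spectrum fit recovers the pure tilt-dominated (q^-2) limit", {
  sp <- surface_spec(25, 25, 16, KC_true = 1e-4, chi_true = 5,
                     n_frames = 400, seed = 14)
  # KC_true must be > 0 for the generator; 1e-4 kBT is negligible vs chi q^2
  fit <- bending_modulus_spectrum(generate_height_frames(sp))
  expect_lt(abs(fit$chi_s - 5) / 5, 0.10)
  expect_lt(fit$kc, 0.5)  # consistent with (near) zero bending rigidity
})

test_that("identical flat frames cannot be fitted (zero spectrum)", {
  flat <- structure(list(fields = replicate(5, matrix(0, 16, 16),
                                            simplify = FALSE),
                         Lx = 20, Ly = 20, n_grid = 16, temperature = 298),
                    class = "height_fields")
  expect_error(bending_modulus_spectrum(flat), "usable q shells")
})

test_that("bending energy matches the single-mode closed form to < 0.1%", {
  L <- 10; a <- 0.3; KC <- 20
  pts <- expand.grid(x = seq(0, L, length.out = 12)[-12],
                     y = seq(0, L, length.out = 12)[-12])
  z <- a * sin(2 * pi * pts$x / L)
  hf <- fit_height_field(cbind(pts$x, pts$y, z), L, L)
  e <- bending_energy(hf, KC, temperature = 298)
  closed <- KC * kBT_kJmol(298) / 2 * a^2 * (2 * pi / L)^4 * L^2 / 2
  expect_lt(abs(as.numeric(e) - closed) / closed, 1e-3)

  # exactly linear in KC; flat surface costs nothing
  e2 <- bending_energy(hf, 2 * KC, temperature = 298)
  expect_equal(as.numeric(e2), 2 * as.numeric(e), tolerance = 1e-12)
  flat <- fit_height_field(cbind(pts$x, pts$y, 1.7), L, L)
  expect_equal(as.numeric(bending_energy(flat, KC)), 0, tolerance = 1e-20)

  # the Monge-gauge correction is small for small slopes
  em <- bending_energy(hf, KC, curvature = "monge")
  expect_equal(as.numeric(em), closed, tolerance = 0.05)
})

test_that("bending-energy profile peaks at the deformed window and scales quadratically", {
  L <- 10; N <- 12
  gx <- (seq_len(N) - 1) / N * L
  mesh <- expand.grid(x = gx, y = gx)
  bump <- function(amp) {
    f <- matrix(amp * sin(2 * pi * mesh$x / L) * cos(2 * pi * mesh$y / L), N, N)
    structure(list(fields = list(f, f), Lx = L, Ly = L, n_grid = N,
                   temperature = 298), class = "height_fields")
  }
  prof <- bending_profile(list(`0.4` = bump(0.05), `1.2` = bump(0.5),
                               `2.0` = bump(0.1)), KC = 20)
  expect_equal(prof$z[which.max(prof$e_bend)], 1.2)
  expect_true(all(prof$flagged))  # 2 frames < 10 per window

  p1 <- bending_profile(list(`1` = bump(0.2)), KC = 20)
  p2 <- bending_profile(list(`1` = bump(0.4)), KC = 20)
  expect_equal(p2$e_bend, 4 * p1$e_bend, tolerance = 1e-6)
})

test_that("mid-surface fitting from headgroup coordinates supports the spectrum path", {
  # two leaflets sampling the same gentle undulation +/- half thickness
  set.seed(20)
  L <- 20; n_mol <- 36
  mk_frame <- function() {
    xu <- runif(n_mol, 0, L); yu <- runif(n_mol, 0, L)
    xl <- runif(n_mol, 0, L); yl <- runif(n_mol, 0, L)
    und <- function(x, y) 0.2 * sin(2 * pi * x / L) + 0.1 * cos(2 * pi * y / L)
    up <- cbind(xu, yu, 4 + und(xu, yu))
    lo <- cbind(xl, yl, 0 + und(xl, yl))
    rbind(up, lo)
  }
  frames <- frame_ensemble(lapply(1:4, function(i) mk_frame()), c(L, L, 8))
  chains <- c(lapply(seq_len(n_mol), function(i) rep(i, 4) + c(0, 0, 0, 0)),
              lapply(seq_len(n_mol), function(i) rep(n_mol + i, 4)))
  # chains need >= 4 distinct atoms for the topology: reuse headgroup index
  topo <- chain_topology(
    chains = lapply(seq_len(2 * n_mol), function(i) c(i, i, i, i)),
    headgroup_atoms = seq_len(2 * n_mol))
  spec <- memperm:::midsurface_fields(frames, topo, n_grid = 8)
  expect_length(spec$fields, 4)
  expect_true(all(vapply(spec$fields, function(m) all(is.finite(m)), logical(1))))
})
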