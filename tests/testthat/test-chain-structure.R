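test_that("order parameter identities: aligned, in-plane, and z-rotation invariance", {
  n <- 6
  aligned <- fixture_ch_chain(matrix(rep(c(0, 0, 1), n), ncol = 3, byrow = TRUE))
  s <- deuterium_order(aligned$frames, aligned$topology)
  expect_equal(s$abs_scd, rep(1, n))

  # C-H in the xy-plane: cos(theta) = 0, SCD = -1/2, |SCD| = 1/2
  phis <- seq(0, 2 * pi, length.out = n + 1)[1:n]
  inplane <- fixture_ch_chain(cbind(cos(phis), sin(phis), 0))
  s2 <- deuterium_order(inplane$frames, inplane$topology)
  expect_equal(s2$scd, rep(-0.5, n))
  expect_equal(s2$abs_scd, rep(0.5, n))

  # rotating the whole system about z leaves the profile unchanged
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot <- inplane$frames$coords[[1]] %*% t(R)
  fr_rot <- frame_ensemble(list(rot), inplane$frames$box[1, ])
  s3 <- deuterium_order(fr_rot, inplane$topology)
  expect_equal(s3$scd, s2$scd, tolerance = 1e-12)
})

test_that("isotropic C-H vectors give |SCD| at the sampling-noise floor", {
  ch <- generate_chain_frames(chain_spec(313, 16, 0, 0.2, seed = 17))
  s <- deuterium_order(ch$frames, ch$topology)  # ~1e4 vectors pooled
  expect_lt(abs(stats::weighted.mean(s$scd, s$n_samples)), 0.02)
  # each per-carbon estimate stays at its own (larger) noise floor
  expect_true(all(s$abs_scd <= 3 * sqrt(0.2 / min(s$n_samples))))
})

test_that("order-parameter recovery from the Watson chain fixture", {
  ch <- generate_chain_frames(chain_spec(400, 16, 0.45, 0.1, seed = 23))
  s <- deuterium_order(ch$frames, ch$topology)
  # per-carbon: 800 vectors, var(P2) < 0.2 (the isotropic bound), 3 sigma
  expect_true(all(abs(s$abs_scd - 0.45) < 3 * sqrt(0.2 / min(s$n_samples))))
  # pooled over the whole chain the target is recovered tightly
  expect_lt(abs(stats::weighted.mean(s$abs_scd, s$n_samples) - 0.45), 0.01)
})

test_that("united-atom reconstruction and C-C approximation produce sane profiles", {
  ch <- generate_chain_frames(chain_spec(50, 12, 0.45, 0.0, seed = 3))
  topo_ua <- chain_topology(ch$topology$chains, ch_bonds = "reconstruct")
  expect_message(s_rec <- deuterium_order(ch$frames, topo_ua),
                 "skipped")  # head carbon has no reconstructable H
  expect_true(all(is.finite(s_rec$abs_scd)))
  expect_true(all(s_rec$abs_scd <= 1))
  s_cc <- deuterium_order(ch$frames, topo_ua, mode = "cc")
  expect_true(all(s_cc$abs_scd <= 0.5 + 1e-12))
})

test_that("gauche fraction: all-trans, all-gauche, and Bernoulli recovery", {
  tr <- generate_chain_frames(chain_spec(30, 10, 0.4, 0, seed = 1))
  g0 <- gauche_fraction(tr$frames, tr$topology)
  expect_equal(g0$gauche, rep(0, 7))

  ga <- generate_chain_frames(chain_spec(30, 10, 0.4, 1, seed = 1))
  g1 <- gauche_fraction(ga$frames, ga$topology)
  expect_equal(g1$gauche, rep(1, 7))

  # gauche + trans = 1: every defined sample is one or the other
  mid <- generate_chain_frames(chain_spec(100, 10, 0.4, 0.3, seed = 5))
  g <- gauche_fraction(mid$frames, mid$topology)
  expect_true(all(g$gauche >= 0 & g$gauche <= 1))
  expect_equal(g$n_samples + g$n_excluded, rep(100L, 7))
})

test_that("cavity density equals the brute-force grid oracle exactly", {
  set.seed(11)
  box <- c(1, 1, 2)
  xyz <- cbind(runif(25, 0, 1), runif(25, 0, 1), runif(25, 0, 2))
  fr <- frame_ensemble(list(xyz), box)
  got <- cavity_density(fr, gridsize = 0.25, symmetrize = FALSE)
  oracle <- brute_cavity_layers(xyz, box, 0.25)  # 4 x 4 x 8 = 128 cells
  # align oracle layers (absolute z) with the COM-centered output bins
  z0 <- mean(xyz[, 3])
  z_oracle <- (seq_along(oracle) - 0.5) * 0.25 - z0
  ord <- order(round(z_oracle / 0.25))
  expect_equal(got$pcav, oracle[ord], tolerance = 1e-12)
})

test_that("cavity density limits: empty box, fully tiled box, single plane", {
  empty <- frame_ensemble(list(matrix(numeric(0), 0, 3)), c(1, 1, 1))
  pe <- cavity_density(empty, gridsize = 0.25, symmetrize = FALSE)
  expect_true(all(pe$pcav == 1))

  one <- frame_ensemble(list(matrix(c(0.125, 0.125, 0.125), 1, 3)), c(1, 1, 1))
  p1 <- cavity_density(one, gridsize = 0.25, symmetrize = FALSE)
  expect_true(all(p1$pcav[-1] == 1))       # only the slab holding the atom dips
  expect_equal(p1$pcav[1], 1 - 1 / 16)

  # fully tiled: an atom at the center of each of the 4x4x4 cells
  g <- (1:4 - 0.5) * 0.25
  tiles <- as.matrix(expand.grid(x = g, y = g, z = g))
  full <- frame_ensemble(list(tiles), c(1, 1, 1))
  pf <- cavity_density(full, gridsize = 0.25, symmetrize = FALSE)
  expect_true(all(pf$pcav == 0))

  # a single z-plane of atoms empties every other slab
  plane <- as.matrix(expand.grid(x = g, y = g, z = 0.625))
  pp <- cavity_density(frame_ensemble(list(plane), c(1, 1, 1)),
                       gridsize = 0.25, symmetrize = FALSE)
  expect_equal(sum(pp$pcav == 0), 1)
  expect_equal(sum(pp$pcav == 1), 3)
})

test_that("phase classification applies the gel/fluid thresholds and reports conflicts", {
  mk_scd <- function(v) {
    out <- tibble::tibble(species = "x", carbon = 1:12, scd = v, abs_scd = v,
                          se = 0.01, n_samples = 100L)
    class(out) <- c("scd_profile", class(out)); out
  }
  mk_g <- function(v) {
    out <- tibble::tibble(species = "x", dihedral_index = 1:9, gauche = v,
                          se = 0.01, n_samples = 100L, n_excluded = 0L)
    class(out) <- c("gauche_profile", class(out)); out
  }
  gel <- classify_phase(mk_scd(0.45), mk_g(0.10), KA = 900, chi = 15)
  expect_equal(gel$verdict, "S")
  expect_true(all(gel$evidence$points_to == "S"))

  fluid <- classify_phase(mk_scd(0.20), mk_g(0.25))
  expect_equal(fluid$verdict, "Ld")

  mixed <- classify_phase(mk_scd(0.35), mk_g(0.20))
  expect_equal(mixed$verdict, "conflicting")
  expect_setequal(unique(mixed$evidence$points_to), c("S", "Ld"))
})
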