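# Independent brute-force oracles used to pin down the fast implementations.

# O(n^2) autocovariance, unbiased normalization -- reference for force_acf()
direct_acf <- function(f, max_lag = length(f) - 1) {
  x <- f - mean(f)
  n <- length(x)
  vapply(0:max_lag, function(k) {
    sum(x[1:(n - k)] * x[(1 + k):n]) / (n - k)
  }, numeric(1))
}

# Direct double-sum discrete Fourier transform of a surface -- reference for
# the FFT in height_spectrum(); returns Lx*Ly*|h_q|^2 for DFT index (m, n)
direct_mode_power <- function(h, m, n, Lx, Ly) {
  N <- nrow(h)
  s <- 0 + 0i
  for (a in 0:(N - 1)) {
    for (b in 0:(N - 1)) {
      s <- s + h[a + 1, b + 1] * exp(-2i * pi * (m * a + n * b) / N)
    }
  }
  Lx * Ly * Mod(s / N^2)^2
}

# Triple-loop grid occupancy -- reference for cavity_density() on small boxes.
# Returns the per-layer empty-cell fraction in absolute z order.
brute_cavity_layers <- function(xyz, box, gridsize) {
  nx <- floor(box[1] / gridsize); ny <- floor(box[2] / gridsize)
  nz <- floor(box[3] / gridsize)
  w <- sweep(xyz, 2, box, function(x, b) x - floor(x / b) * b)
  empty <- numeric(nz)
  for (k in seq_len(nz)) {
    n_empty <- 0
    for (j in seq_len(ny)) {
      for (i in seq_len(nx)) {
        lo <- (c(i, j, k) - 1) * gridsize
        hi <- c(i, j, k) * gridsize
        occ <- FALSE
        for (a in seq_len(nrow(w))) {
          if (all(w[a, ] >= lo) && all(w[a, ] < hi)) { occ <- TRUE; break }
        }
        if (!occ) n_empty <- n_empty + 1
      }
    }
    empty[k] <- n_empty / (nx * ny)
  }
  empty
}

# Hand-built four-carbon chain with explicit hydrogens at given C-H
# directions; returns frames + topology for identity tests.
fixture_ch_chain <- function(h_dirs, box = c(5, 5, 5)) {
  n <- nrow(h_dirs)
  stopifnot(n >= 4)
  carbons <- cbind(rep(2.5, n), rep(2.5, n), seq(4, by = -0.15, length.out = n))
  hyd <- carbons + 0.109 * h_dirs
  xyz <- rbind(carbons, hyd)
  frames <- frame_ensemble(list(xyz), box)
  topo <- chain_topology(list(1:n), ch_bonds = cbind(1:n, n + (1:n)))
  list(frames = frames, topology = topo)
}
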