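#' Synthetic membrane fixtures with known ground truth
#'
#' Every estimator in the package has a parameter-recovery test driven by
#' these generators: alkyl chains with a tunable orientational order
#' parameter and gauche probability, headgroup height fields sampled from a
#' Helfrich q^-4 / q^-2 fluctuation spectrum with known bending modulus and
#' tilt term, per-molecule area series with a known compressibility, and
#' Ornstein-Uhlenbeck constraint-force series with a known mean-force
#' profile and known local diffusivity. Each generator seeds its own
#' random-number stream (no global state is disturbed) and attaches the
#' ground truth as a `ground_truth` attribute.
#'
#' @name synthetic_membrane
NULL

# Run code under a local RNG stream without touching the caller's state.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# --- Watson-type axial orientation distribution ------------------------------

# Mean of P2(u) = (3u^2 - 1)/2 under density f(u) prop exp(kappa * u^2) on
# [-1, 1]. Monotone in kappa: -> -1/2 as kappa -> -Inf, 0 at kappa = 0,
# -> 1 as kappa -> +Inf.
watson_p2_mean <- function(kappa) {
  if (abs(kappa) < 1e-12) return(0)
  z <- stats::integrate(function(u) exp(kappa * (u^2 - 1)), -1, 1,
                        rel.tol = 1e-12)$value
  m2 <- stats::integrate(function(u) u^2 * exp(kappa * (u^2 - 1)), -1, 1,
                         rel.tol = 1e-12)$value / z
  (3 * m2 - 1) / 2
}

# Invert watson_p2_mean for a target second moment in (-0.5, 1).
watson_kappa_for_p2 <- function(p2) {
  if (p2 == 0) return(0)
  lo <- -1; hi <- 1
  while (watson_p2_mean(lo) > p2 && lo > -1e4) lo <- lo * 2
  while (watson_p2_mean(hi) < p2 && hi < 1e4) hi <- hi * 2
  stats::uniroot(function(k) watson_p2_mean(k) - p2, c(lo, hi),
                 tol = 1e-10)$root
}

# Rejection-sample u = cos(theta) from f(u) prop exp(kappa u^2).
sample_watson_cos <- function(n, kappa) {
  out <- numeric(0)
  # envelope: uniform on [-1,1]; f(u)/max(f) <= 1
  shift <- if (kappa > 0) kappa else 0
  while (length(out) < n) {
    m <- max(64L, ceiling((n - length(out)) * 2.5))
    u <- stats::runif(m, -1, 1)
    acc <- stats::runif(m) < exp(kappa * u^2 - shift)
    out <- c(out, u[acc])
  }
  out[seq_len(n)]
}

# Uniformly random azimuth around z for a given cos(theta).
axial_unit_vectors <- function(cos_theta) {
  n <- length(cos_theta)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - cos_theta^2))
  cbind(s * cos(phi), s * sin(phi), cos_theta)
}

# --- Alkyl-chain fixture -----------------------------------------------------

#' Specification for a synthetic alkyl-chain ensemble
#'
#' @param n_chains number of chains
#' @param n_carbons carbons per chain (>= 4)
#' @param order_param_target target C-H orientational order,
#'   the mean of P2(cos theta) in `[0, 1]`; the downstream deuterium order
#'   parameter recovers this value
#' @param gauche_prob Bernoulli probability that any backbone dihedral is
#'   gauche (|phi| < 120 deg) rather than trans
#' @param n_frames number of frames to emit
#' @param seed integer seed
#' @return a `chain_spec` list
#' @export
chain_spec <- function(n_chains, n_carbons, order_param_target, gauche_prob,
                       n_frames = 1, seed = 1) {
  if (n_carbons < 4) stop("n_carbons must be >= 4", call. = FALSE)
  if (order_param_target < 0 || order_param_target > 1) {
    stop("order_param_target must lie in [0, 1]", call. = FALSE)
  }
  if (gauche_prob < 0 || gauche_prob > 1) {
    stop("gauche_prob must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n_chains = as.integer(n_chains),
                 n_carbons = as.integer(n_carbons),
                 order_param_target = order_param_target,
                 gauche_prob = gauche_prob,
                 n_frames = as.integer(n_frames),
                 seed = as.integer(seed)),
            class = "chain_spec")
}

# Extend a backbone by one atom from internal coordinates (bond r, bond
# angle theta at C, dihedral phi for A-B-C-D).
nerf_extend <- function(A, B, C, r, theta, phi) {
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- pracma::cross(ab, bc); n <- n / sqrt(sum(n^2))
  m <- pracma::cross(n, bc)
  d <- r * c(-cos(theta), sin(theta) * cos(phi), sin(theta) * sin(phi))
  C + d[1] * bc + d[2] * m + d[3] * n
}

#' Generate a synthetic alkyl-chain ensemble
#'
#' Chains are laid out on a square lattice. Backbones are built with ideal
#' bond geometry (0.153 nm bonds, 111 deg angles) and a dihedral sequence
#' drawn Bernoulli(`gauche_prob`) between gauche (+/-60 deg) and trans
#' (180 deg). Two explicit hydrogens are attached to every carbon, with C-H
#' directions drawn from a Watson-type axial distribution whose second
#' moment about the z axis equals `order_param_target` exactly (targets of
#' 0 and 1 are the isotropic and perfectly aligned limits).
#'
#' @param spec a [chain_spec()]
#' @return a list with `frames` (a [frame_ensemble()]), `topology`
#'   (a [chain_topology()]); ground truth (targets plus the realized gauche
#'   fraction) is attached as attribute `ground_truth`
#' @export
generate_chain_frames <- function(spec) {
  stopifnot(inherits(spec, "chain_spec"))
  nc <- spec$n_carbons; nch <- spec$n_chains
  atoms_per_chain <- nc + 2L * nc  # carbons + 2 H each
  r_cc <- 0.153; r_ch <- 0.109; theta <- 111 * pi / 180
  side <- ceiling(sqrt(nch)); pitch <- 0.8
  box <- c(side * pitch + 2, side * pitch + 2, nc * r_cc + 3)

  with_local_seed(spec$seed, {
    gauche_flags <- matrix(stats::runif(nch * (nc - 3)) < spec$gauche_prob,
                           nrow = nch)
    kappa <- if (spec$order_param_target >= 1) Inf else
      watson_kappa_for_p2(spec$order_param_target)

    build_frame <- function() {
      xyz <- matrix(0, nch * atoms_per_chain, 3)
      for (j in seq_len(nch)) {
        base <- (j - 1) * atoms_per_chain
        x0 <- ((j - 1) %% side) * pitch + 1
        y0 <- ((j - 1) %/% side) * pitch + 1
        P <- matrix(0, nc, 3)
        P[1, ] <- c(x0, y0, nc * r_cc + 1.5)
        P[2, ] <- P[1, ] + c(0, 0, -r_cc)
        P[3, ] <- P[2, ] + r_cc * c(sin(theta), 0, cos(theta))
        if (nc >= 4) {
          for (i in 4:nc) {
            phi <- if (gauche_flags[j, i - 3]) {
              sample(c(-1, 1), 1) * pi / 3
            } else pi
            P[i, ] <- nerf_extend(P[i - 3, ], P[i - 2, ], P[i - 1, ],
                                  r_cc, theta, phi)
          }
        }
        xyz[base + seq_len(nc), ] <- P
        u <- if (is.infinite(kappa)) {
          matrix(rep(c(0, 0, 1), each = 2 * nc), ncol = 3)
        } else {
          axial_unit_vectors(sample_watson_cos(2 * nc, kappa))
        }
        for (i in seq_len(nc)) {
          xyz[base + nc + 2 * i - 1, ] <- P[i, ] + r_ch * u[2 * i - 1, ]
          xyz[base + nc + 2 * i, ]     <- P[i, ] + r_ch * u[2 * i, ]
        }
      }
      xyz
    }
    coords <- purrr::map(seq_len(spec$n_frames), function(f) build_frame())
    frames <- frame_ensemble(coords, box)

    chains <- purrr::map(seq_len(nch), function(j) {
      (j - 1L) * atoms_per_chain + seq_len(nc)
    })
    ch_bonds <- do.call(rbind, purrr::map(seq_len(nch), function(j) {
      base <- (j - 1L) * atoms_per_chain
      cbind(rep(base + seq_len(nc), each = 2),
            base + nc + seq_len(2L * nc))
    }))
    topo <- chain_topology(chains, ch_bonds = ch_bonds,
                           species = rep("synthetic", nch))
    out <- list(frames = frames, topology = topo)
    attr(out, "ground_truth") <- list(
      order_param_target = spec$order_param_target,
      gauche_prob = spec$gauche_prob,
      gauche_fraction_realized = mean(gauche_flags),
      gauche_flags = gauche_flags
    )
    out
  })
}

# --- Helfrich height-field fixture -------------------------------------------

#' Specification for a synthetic undulating surface ensemble
#'
#' @param Lx,Ly lateral box size in nm
#' @param n_grid sampling points per axis (>= 8)
#' @param KC_true bending modulus, kBT units (> 0)
#' @param chi_true tilt/protrusion term, kBT/nm^2 (>= 0)
#' @param temperature K (recorded; moduli are in kBT units so the sampled
#'   field does not depend on it)
#' @param n_frames number of surfaces
#' @param seed integer seed
#' @return a `surface_spec` list
#' @export
surface_spec <- function(Lx, Ly, n_grid, KC_true, chi_true = 0,
                         temperature = 298, n_frames = 1000, seed = 1) {
  if (KC_true <= 0) stop("KC_true must be positive", call. = FALSE)
  if (chi_true < 0) stop("chi_true must be non-negative", call. = FALSE)
  if (n_grid < 8) stop("n_grid must be >= 8", call. = FALSE)
  structure(list(Lx = Lx, Ly = Ly, n_grid = as.integer(n_grid),
                 KC_true = KC_true, chi_true = chi_true,
                 temperature = temperature, n_frames = as.integer(n_frames),
                 seed = as.integer(seed)),
            class = "surface_spec")
}

# Wavevector magnitude for DFT indices m, n (0-based, wrapped).
dft_q <- function(m, n, Lx, Ly, N) {
  mm <- ifelse(m > N / 2, m - N, m)
  nn <- ifelse(n > N / 2, n - N, n)
  2 * pi * sqrt((mm / Lx)^2 + (nn / Ly)^2)
}

#' Generate surfaces from a Helfrich fluctuation spectrum
#'
#' Each allowed wavevector `q` receives an independent complex Gaussian
#' Fourier amplitude with `Lx*Ly*<|h_q|^2> = kBT / (KC q^4 + chi q^2)`
#' (kBT = 1 in kBT energy units), Hermitian-symmetrized so the real-space
#' surface is real. Surfaces are returned on an `n_grid x n_grid` mesh.
#'
#' @param spec a [surface_spec()]
#' @return an object of class `height_fields`: list with `fields` (list of
#'   matrices, nm), `Lx`, `Ly`, `n_grid`, `temperature`; ground truth in
#'   attribute `ground_truth`
#' @export
generate_height_frames <- function(spec) {
  stopifnot(inherits(spec, "surface_spec"))
  N <- spec$n_grid
  A <- spec$Lx * spec$Ly
  mmax <- (N - 1L) %/% 2L  # exclude Nyquist row/col: every kept mode is paired
  with_local_seed(spec$seed, {
    fields <- purrr::map(seq_len(spec$n_frames), function(f) {
      H <- matrix(0 + 0i, N, N)
      for (m in 0:mmax) {
        for (n in (-mmax):mmax) {
          if (m == 0 && n <= 0) next  # (0,0) excluded; half-plane + conjugates
          q <- 2 * pi * sqrt((m / spec$Lx)^2 + (n / spec$Ly)^2)
          v <- 1 / (A * (spec$KC_true * q^4 + spec$chi_true * q^2))
          re <- stats::rnorm(1, 0, sqrt(v / 2))
          im <- stats::rnorm(1, 0, sqrt(v / 2))
          mi <- m %% N + 1L; ni <- n %% N + 1L
          H[mi, ni] <- complex(real = re, imaginary = im)
          H[(-m) %% N + 1L, (-n) %% N + 1L] <- complex(real = re, imaginary = -im)
        }
      }
      Re(stats::fft(H, inverse = TRUE))  # h(r) = sum_q h_q exp(iqr)
    })
    out <- structure(
      list(fields = fields, Lx = spec$Lx, Ly = spec$Ly, n_grid = N,
           temperature = spec$temperature),
      class = "height_fields"
    )
    attr(out, "ground_truth") <- list(KC = spec$KC_true, chi = spec$chi_true)
    out
  })
}

#' @export
print.height_fields <- function(x, ...) {
  cat(sprintf("<height_fields> %d frames, %dx%d grid, %.1f x %.1f nm\n",
              length(x$fields), x$n_grid, x$n_grid, x$Lx, x$Ly))
  invisible(x)
}

# --- Area-fluctuation fixture ------------------------------------------------

#' Generate a per-molecule area time series with known compressibility
#'
#' Samples are Gaussian with `var(Amol) = kBT * <Amol> / (N * KA_true)`,
#' the stationary fluctuation law that the area-compressibility estimator
#' inverts, so the estimator applied to the output recovers `KA_true`.
#'
#' @param mean_area_per_mol mean lateral area per molecule, nm^2
#' @param KA_true area compressibility modulus, mN/m (> 0)
#' @param N molecules per leaflet
#' @param temperature K
#' @param n_frames series length
#' @param seed integer seed
#' @return an `area_series` tibble with columns `frame`, `area_per_mol`;
#'   `N` and `temperature` attributes and `ground_truth` attached
#' @export
generate_area_series <- function(mean_area_per_mol, KA_true, N = 64,
                                 temperature = 298, n_frames = 10000,
                                 seed = 1) {
  if (KA_true <= 0) stop("KA_true must be positive", call. = FALSE)
  ka_kJ <- KA_true / ka_to_mNm(1)  # mN/m -> kJ/mol/nm^2
  v <- kBT_kJmol(temperature) * mean_area_per_mol / (N * ka_kJ)  # nm^4
  with_local_seed(seed, {
    a <- stats::rnorm(n_frames, mean_area_per_mol, sqrt(v))
    out <- tibble::tibble(frame = seq_len(n_frames), area_per_mol = a)
    attr(out, "N") <- as.integer(N)
    attr(out, "temperature") <- temperature
    attr(out, "ground_truth") <- list(KA = KA_true,
                                      mean_area = mean_area_per_mol,
                                      variance = v)
    class(out) <- c("area_series", class(out))
    out
  })
}

# --- Constraint-force fixture ------------------------------------------------

#' Specification for synthetic constraint-force windows
#'
#' @param z_values strictly increasing constraint distances from the
#'   membrane center, nm
#' @param mean_force_profile function of z returning the mean force on the
#'   permeant, kJ/mol/nm (positive = toward bulk); or a single number
#'   applied at all z
#' @param force_variance stationary variance of the force fluctuation,
#'   (kJ/mol/nm)^2
#' @param correlation_time fluctuation correlation time tau, ps (> 0)
#' @param dt sampling interval, ps (must resolve tau: dt < tau)
#' @param n_steps samples per window
#' @param temperature K
#' @param n_replicates independent replicate series per z (replicates model
#'   constrained runs started from independent configurations)
#' @param seed integer seed
#' @return a `force_spec` list
#' @export
force_spec <- function(z_values, mean_force_profile, force_variance,
                       correlation_time, dt, n_steps, temperature = 298,
                       n_replicates = 1, seed = 1) {
  if (any(diff(z_values) <= 0)) {
    stop("z_values must be strictly increasing", call. = FALSE)
  }
  if (correlation_time <= 0) stop("correlation_time must be positive", call. = FALSE)
  if (dt >= correlation_time) {
    stop("dt must be smaller than the correlation time (discretization error)",
         call. = FALSE)
  }
  if (is.numeric(mean_force_profile) && length(mean_force_profile) == 1) {
    f0 <- mean_force_profile
    mean_force_profile <- function(z) rep(f0, length(z))
  }
  stopifnot(is.function(mean_force_profile))
  structure(list(z_values = z_values, mean_force_profile = mean_force_profile,
                 force_variance = force_variance,
                 correlation_time = correlation_time, dt = dt,
                 n_steps = as.integer(n_steps), temperature = temperature,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "force_spec")
}

# Exact discrete-time Ornstein-Uhlenbeck update: stationary statistics hold
# at any dt (not an Euler scheme).
ou_series <- function(n, mu, sigma2, tau, dt) {
  a <- exp(-dt / tau)
  s <- sqrt(sigma2 * (1 - a^2))
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sqrt(sigma2))
  innov <- stats::rnorm(n - 1, 0, s)
  for (i in 2:n) x[i] <- x[i - 1] * a + innov[i - 1]
  x + mu
}

#' Generate Ornstein-Uhlenbeck constraint-force windows
#'
#' Each window's series is `mean_force_profile(z)` plus a stationary OU
#' fluctuation with variance `force_variance` and correlation time
#' `correlation_time`. The OU autocorrelation integral is `sigma^2 * tau`,
#' so the ground-truth local diffusivity is `D(z) = (RT)^2 / (sigma^2 tau)`
#' (nm^2/ps with forces in kJ/mol/nm and times in ps). The ground-truth free
#' energy is the analytic integral of the mean-force profile from the
#' outermost z inward.
#'
#' @param spec a [force_spec()]
#' @return a `force_windows` list of `force_window` objects (fields `z`,
#'   `forces`, `dt`, `temperature`, `replicate`), with `ground_truth`
#'   attached (`D` in nm^2/ps, `dG` in kJ/mol on `z_values`)
#' @export
generate_force_windows <- function(spec) {
  stopifnot(inherits(spec, "force_spec"))
  RT <- kBT_kJmol(spec$temperature)
  D_true <- RT^2 / (spec$force_variance * spec$correlation_time)
  zmax <- max(spec$z_values)
  dG_true <- vapply(spec$z_values, function(z) {
    if (z >= zmax) return(0)
    stats::integrate(spec$mean_force_profile, z, zmax,
                     rel.tol = 1e-10)$value
  }, numeric(1))
  with_local_seed(spec$seed, {
    windows <- purrr::flatten(purrr::map(spec$z_values, function(z) {
      mu <- spec$mean_force_profile(z)
      purrr::map(seq_len(spec$n_replicates), function(r) {
        structure(
          list(z = z,
               forces = ou_series(spec$n_steps, mu, spec$force_variance,
                                  spec$correlation_time, spec$dt),
               dt = spec$dt, temperature = spec$temperature, replicate = r),
          class = "force_window"
        )
      })
    }))
    out <- structure(windows, class = "force_windows")
    attr(out, "ground_truth") <- list(
      D = D_true, dG = tibble::tibble(z = spec$z_values, dG = dG_true),
      force_variance = spec$force_variance, tau = spec$correlation_time
    )
    out
  })
}

#' @export
print.force_windows <- function(x, ...) {
  z <- vapply(x, function(w) w$z, numeric(1))
  cat(sprintf("<force_windows> %d windows at %d z values (%.2f..%.2f nm), %d steps each\n",
              length(x), length(unique(z)), min(z), max(z),
              length(x[[1]]$forces)))
  invisible(x)
}
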