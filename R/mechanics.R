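#' Fluctuation-based membrane mechanics
#'
#' Area compressibility from area fluctuations, molecular tilt modulus from
#' Boltzmann inversion of the tilt-angle distribution, bending modulus from
#' the height-fluctuation spectrum, and Helfrich bending energies of fitted
#' height fields.
#'
#' @name mechanics
NULL

#' Area compressibility modulus from area fluctuations
#'
#' `KA = kBT * <Amol> / (N * var(Amol))`, reported in mN/m. The uncertainty
#' comes from block averaging (contiguous blocks re-estimated
#' independently), which is robust to the serial correlation of
#' simulation series.
#'
#' @param areas an `area_series` tibble (see [generate_area_series()]) or
#'   any data frame with an `area_per_mol` column (nm^2)
#' @param temperature K; taken from the series attribute when omitted
#' @param N molecules per leaflet; taken from the series attribute when
#'   omitted
#' @param n_blocks blocks for the uncertainty estimate
#' @return an object of class `ka_estimate` with fields `KA` (mN/m), `se`,
#'   `mean_area`, `variance`, `N`, `temperature`, `n_frames`
#' @export
area_compressibility <- function(areas, temperature = NULL, N = NULL,
                                 n_blocks = 5) {
  a <- areas$area_per_mol
  if (is.null(a)) stop("areas must have an 'area_per_mol' column", call. = FALSE)
  temperature <- temperature %||% attr(areas, "temperature") %||% 298
  N <- N %||% attr(areas, "N") %||%
    stop("N (molecules per leaflet) required", call. = FALSE)
  n <- length(a)
  if (n < 2) stop("need at least 2 frames", call. = FALSE)
  if (n < 100) warning("fewer than 100 frames: KA estimate is unreliable",
                       call. = FALSE)
  v <- stats::var(a)
  est <- function(x) {
    vv <- stats::var(x)
    if (vv == 0) return(Inf)
    ka_to_mNm(kBT_kJmol(temperature) * mean(x) / (N * vv))
  }
  KA <- est(a)
  se <- NA_real_
  if (is.finite(KA) && n >= 2 * n_blocks) {
    blocks <- split(a, cut(seq_len(n), n_blocks, labels = FALSE))
    bk <- vapply(blocks, est, numeric(1))
    se <- stats::sd(bk) / sqrt(n_blocks)
  }
  structure(list(KA = KA, se = se, mean_area = mean(a), variance = v,
                 N = N, temperature = temperature, n_frames = n,
                 n_blocks = n_blocks),
            class = "ka_estimate")
}

#' @export
print.ka_estimate <- function(x, ...) {
  cat(sprintf("KA = %.1f +/- %.1f mN/m  (<Amol> = %.4f nm^2, N = %d, %d frames)\n",
              x$KA, x$se, x$mean_area, x$N, x$n_frames))
  invisible(x)
}

#' Molecular tilt angles of alkyl chains
#'
#' The tilt is the angle between the bilayer normal and the chain direction
#' vector connecting the first and the second-last carbon, unwrapped across
#' periodic boundaries along the backbone. Lower-leaflet chains are measured
#' against -z so tilt is always relative to the outward normal.
#'
#' @param frames a [frame_ensemble()]
#' @param topo a [chain_topology()]
#' @return a tibble with `frame`, `chain`, `alpha` (rad)
#' @export
tilt_angles <- function(frames, topo) {
  stopifnot(inherits(frames, "frame_ensemble"), inherits(topo, "chain_topology"))
  leaf <- assign_leaflets(frames, topo)
  purrr::map_dfr(seq_len(frames$n_frames), function(f) {
    xyz <- frames$coords[[f]]; box <- frames$box[f, ]
    lf <- leaf$leaflet[leaf$frame == f]
    alpha <- vapply(seq_along(topo$chains), function(j) {
      ch <- topo$chains[[j]]
      v <- c(0, 0, 0)
      for (i in seq_len(length(ch) - 2)) {  # first -> second-last, bonded steps
        v <- v + min_image(xyz[ch[i], ], xyz[ch[i + 1], ], box)
      }
      u <- v / sqrt(sum(v^2))
      sgn <- if (lf[j] == "upper") -1 else 1  # chains point inward from the head
      acos(pmin(1, pmax(-1, sgn * u[3])))
    }, numeric(1))
    tibble::tibble(frame = f, chain = seq_along(topo$chains), alpha = alpha)
  })
}

#' Molecular tilt modulus by Boltzmann inversion
#'
#' Histograms the tilt angles, forms the tilt free energy
#' `F(alpha) = -kBT ln[P(alpha)/sin(alpha)]` (the sin removes the spherical
#' Jacobian), and fits `F = F(alpha0) + (chi/2)(alpha - alpha0)^2` over the
#' window where `F <= min(F) + 2 kBT`. Returns chi in kBT/rad^2.
#'
#' @param x either a tibble with an `alpha` column (rad), a bare numeric
#'   vector of angles, or a [frame_ensemble()] (then `topo` is required)
#' @param topo a [chain_topology()] when `x` is a frame ensemble
#' @param n_bins histogram bins over the sampled range
#' @param window_kBT half-depth of the fit window in kBT
#' @return an object of class `tilt_fit`: `chi` (kBT/rad^2), `se`,
#'   `alpha0` (rad), `r_squared`, `n_fit_points`, and the `distribution`
#'   tibble (`alpha`, `p`, `f` in kBT)
#' @export
tilt_modulus <- function(x, topo = NULL, n_bins = 72, window_kBT = 2) {
  alpha <- if (inherits(x, "frame_ensemble")) {
    if (is.null(topo)) stop("topo required with a frame ensemble", call. = FALSE)
    tilt_angles(x, topo)$alpha
  } else if (is.data.frame(x)) x$alpha else as.numeric(x)
  alpha <- alpha[is.finite(alpha)]
  if (length(alpha) < 100) stop("need at least 100 tilt samples", call. = FALSE)
  if (stats::sd(alpha) < 1e-6) {
    stop("degenerate tilt distribution (zero width); modulus undefined",
         call. = FALSE)
  }
  br <- seq(min(alpha), max(alpha), length.out = n_bins + 1)
  h <- graphics::hist(alpha, breaks = br, plot = FALSE)
  da <- diff(br)[1]
  p <- h$counts / (sum(h$counts) * da)   # sum(p * da) = 1
  mid <- h$mids
  ok <- p > 0 & sin(mid) > 0
  f <- rep(NA_real_, length(mid))
  f[ok] <- -log(p[ok] / sin(mid[ok]))    # kBT units
  fmin <- min(f, na.rm = TRUE)
  in_win <- !is.na(f) & f <= fmin + window_kBT
  n_empty <- sum(!ok & mid >= min(mid[in_win]) & mid <= max(mid[in_win]))
  if (n_empty > 0) {
    message("tilt_modulus: ", n_empty, " empty bin(s) inside fit window dropped")
  }
  if (sum(in_win) < 5) {
    stop("fewer than 5 histogram points inside the fit window", call. = FALSE)
  }
  dfit <- data.frame(a = mid[in_win], f = f[in_win])
  fit <- stats::lm(f ~ a + I(a^2), data = dfit)
  co <- stats::coef(fit)
  chi <- 2 * co[[3]]
  se <- 2 * summary(fit)$coefficients[3, 2]
  alpha0 <- if (abs(co[[3]]) > 1e-12) -co[[2]] / (2 * co[[3]]) else NA_real_
  dist <- tibble::tibble(alpha = mid, p = p, f = f)
  structure(list(chi = chi, se = se, alpha0 = alpha0,
                 r_squared = summary(fit)$r.squared,
                 n_fit_points = sum(in_win), n_samples = length(alpha),
                 distribution = dist, window_kBT = window_kBT),
            class = "tilt_fit")
}

#' @export
print.tilt_fit <- function(x, ...) {
  cat(sprintf(
    "tilt modulus chi = %.2f +/- %.2f kBT/rad^2 (alpha0 = %.3f rad, R^2 = %.3f, %d fit points)\n",
    x$chi, x$se, x$alpha0, x$r_squared, x$n_fit_points))
  invisible(x)
}

# --- Truncated Fourier height field ------------------------------------------

hf_basis_terms <- function(basis) {
  g <- expand.grid(m = 0:2, n = 0:2)
  if (basis == "combined") {
    terms <- rbind(
      data.frame(g, trig = "sin"),
      data.frame(g, trig = "cos")
    )
    terms[!(terms$m == 0 & terms$n == 0 & terms$trig == "sin"), ]
  } else {
    # product basis: a_mn sin(2pi m x/Lx) sin(2pi n y/Ly)
    #              + b_mn cos(2pi m x/Lx) cos(2pi n y/Ly)
    terms <- rbind(
      data.frame(g, trig = "sin"),
      data.frame(g, trig = "cos")
    )
    terms[!(terms$trig == "sin" & (terms$m == 0 | terms$n == 0)), ]
  }
}

hf_design <- function(x, y, Lx, Ly, terms, basis) {
  sapply(seq_len(nrow(terms)), function(k) {
    m <- terms$m[k]; n <- terms$n[k]
    if (basis == "combined") {
      th <- 2 * pi * (m * x / Lx + n * y / Ly)
      if (terms$trig[k] == "sin") sin(th) else cos(th)
    } else {
      if (terms$trig[k] == "sin") sin(2 * pi * m * x / Lx) * sin(2 * pi * n * y / Ly)
      else cos(2 * pi * m * x / Lx) * cos(2 * pi * n * y / Ly)
    }
  })
}

#' Fit a truncated Fourier height field to headgroup positions
#'
#' Linear least squares of the periodic basis
#' `sin/cos(2 pi (m x/Lx + n y/Ly))`, `m, n` in 0..2, against the supplied
#' surface points (the identically-zero sine term at m = n = 0 is dropped).
#' The fitted surface is analytic, so curvatures are available in closed
#' form. A separable product basis (`sin(2 pi m x/Lx) sin(2 pi n y/Ly)`,
#' etc.) is available behind `basis = "product"`.
#'
#' @param points a matrix or data frame with columns x, y, z (nm)
#' @param Lx,Ly lateral box size, nm
#' @param basis `"combined"` (default) or `"product"`
#' @return an object of class `height_field_fit`: `coefficients` tibble
#'   (m, n, trig, value), `Lx`, `Ly`, `basis`, `residual_rms` (nm)
#' @export
fit_height_field <- function(points, Lx, Ly, basis = c("combined", "product")) {
  basis <- match.arg(basis)
  pts <- as.matrix(as.data.frame(points)[, 1:3])
  terms <- hf_basis_terms(basis)
  if (nrow(pts) < nrow(terms) + 1) {
    stop("need at least ", nrow(terms) + 1, " surface points", call. = FALSE)
  }
  X <- hf_design(pts[, 1], pts[, 2], Lx, Ly, terms, basis)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("rank-deficient height-field design (points degenerate)", call. = FALSE)
  }
  beta <- qr.coef(qrX, pts[, 3])
  resid <- pts[, 3] - X %*% beta
  structure(list(
    coefficients = tibble::tibble(m = terms$m, n = terms$n, trig = terms$trig,
                                  value = as.numeric(beta)),
    Lx = Lx, Ly = Ly, basis = basis,
    residual_rms = sqrt(mean(resid^2)), n_points = nrow(pts)
  ), class = "height_field_fit")
}

#' Evaluate a fitted height field and its derivatives
#'
#' @param hf a `height_field_fit`
#' @param x,y evaluation coordinates (vectors of equal length), nm
#' @param deriv one of `"h"`, `"lap"` (Laplacian), `"grad"` (list hx, hy),
#'   `"hess"` (list hxx, hxy, hyy)
#' @return numeric vector, or a list of vectors for `"grad"`/`"hess"`
#' @export
eval_height_field <- function(hf, x, y, deriv = c("h", "lap", "grad", "hess")) {
  deriv <- match.arg(deriv)
  co <- hf$coefficients
  acc <- function(fun) {
    out <- 0
    for (k in seq_len(nrow(co))) {
      out <- out + co$value[k] * fun(co$m[k], co$n[k], co$trig[k])
    }
    out
  }
  if (hf$basis == "combined") {
    kx <- function(m) 2 * pi * m / hf$Lx
    ky <- function(n) 2 * pi * n / hf$Ly
    th <- function(m, n) kx(m) * x + ky(n) * y
    base <- function(m, n, tr) if (tr == "sin") sin(th(m, n)) else cos(th(m, n))
    dbase <- function(m, n, tr) if (tr == "sin") cos(th(m, n)) else -sin(th(m, n))
    switch(deriv,
      h = acc(base),
      lap = acc(function(m, n, tr) -(kx(m)^2 + ky(n)^2) * base(m, n, tr)),
      grad = list(
        hx = acc(function(m, n, tr) kx(m) * dbase(m, n, tr)),
        hy = acc(function(m, n, tr) ky(n) * dbase(m, n, tr))
      ),
      hess = list(
        hxx = acc(function(m, n, tr) -kx(m)^2 * base(m, n, tr)),
        hxy = acc(function(m, n, tr) -kx(m) * ky(n) * base(m, n, tr)),
        hyy = acc(function(m, n, tr) -ky(n)^2 * base(m, n, tr))
      ))
  } else {
    kx <- function(m) 2 * pi * m / hf$Lx
    ky <- function(n) 2 * pi * n / hf$Ly
    sx <- function(m, tr) if (tr == "sin") sin(kx(m) * x) else cos(kx(m) * x)
    sy <- function(n, tr) if (tr == "sin") sin(ky(n) * y) else cos(ky(n) * y)
    dsx <- function(m, tr) if (tr == "sin") kx(m) * cos(kx(m) * x) else -kx(m) * sin(kx(m) * x)
    dsy <- function(n, tr) if (tr == "sin") ky(n) * cos(ky(n) * y) else -ky(n) * sin(ky(n) * y)
    base <- function(m, n, tr) sx(m, tr) * sy(n, tr)
    switch(deriv,
      h = acc(base),
      lap = acc(function(m, n, tr) -(kx(m)^2 + ky(n)^2) * base(m, n, tr)),
      grad = list(
        hx = acc(function(m, n, tr) dsx(m, tr) * sy(n, tr)),
        hy = acc(function(m, n, tr) sx(m, tr) * dsy(n, tr))
      ),
      hess = list(
        hxx = acc(function(m, n, tr) -kx(m)^2 * base(m, n, tr)),
        hxy = acc(function(m, n, tr) dsx(m, tr) * dsy(n, tr)),
        hyy = acc(function(m, n, tr) -ky(n)^2 * base(m, n, tr))
      ))
  }
}

#' @export
print.height_field_fit <- function(x, ...) {
  cat(sprintf("<height_field_fit> %s basis, %d coefficients, residual RMS %.4g nm\n",
              x$basis, nrow(x$coefficients), x$residual_rms))
  invisible(x)
}

# --- Height-fluctuation spectrum and bending modulus -------------------------

#' Height-fluctuation power spectrum
#'
#' Fourier-transforms each gridded surface on the periodic box and averages
#' `Lx*Ly*<|h_q|^2>` (DFT amplitudes normalized by the number of grid
#' points) over frames and over modes of equal `|q|`. With the moduli in
#' kBT units the Helfrich expectation is `1/(KC q^4 + chi q^2)` (nm^4).
#'
#' @param fields a `height_fields` object (see [generate_height_frames()]),
#'   or a list of matrices with `Lx`, `Ly` given
#' @param Lx,Ly lateral box size, nm (taken from the object when omitted)
#' @return a tibble of class `fluctuation_spectrum`: `q` (1/nm), `h2`
#'   (nm^4), `se`, `n_modes`, `n_frames`; single-frame input carries
#'   `se = Inf` (no ensemble averaging)
#' @export
height_spectrum <- function(fields, Lx = NULL, Ly = NULL) {
  if (inherits(fields, "height_fields")) {
    Lx <- fields$Lx; Ly <- fields$Ly; flist <- fields$fields
  } else {
    flist <- fields
    if (is.null(Lx) || is.null(Ly)) stop("Lx and Ly required", call. = FALSE)
  }
  N <- nrow(flist[[1]])
  A <- Lx * Ly
  idx <- expand.grid(m = 0:(N - 1), n = 0:(N - 1))
  q <- dft_q(idx$m, idx$n, Lx, Ly, N)
  mmax <- (N - 1) %/% 2
  mm <- ifelse(idx$m > N / 2, idx$m - N, idx$m)
  nn <- ifelse(idx$n > N / 2, idx$n - N, idx$n)
  usable <- q > 0 & abs(mm) <= mmax & abs(nn) <= mmax
  per_frame <- vapply(flist, function(h) {
    hq <- stats::fft(h) / N^2
    as.numeric(A * Mod(hq)^2)
  }, numeric(N * N))
  per_frame <- matrix(per_frame, nrow = N * N)[usable, , drop = FALSE]
  nf <- length(flist)
  qkey <- round(q[usable], 9)
  qu <- sort(unique(qkey))
  gid <- match(qkey, qu)
  cnt <- tabulate(gid, nbins = length(qu))
  shell_frames <- rowsum(per_frame, gid) / cnt  # shell x frame means
  out <- tibble::tibble(
    q = qu,
    h2 = unname(rowMeans(shell_frames)),
    se = if (nf > 1) unname(apply(shell_frames, 1, stats::sd)) / sqrt(nf) else Inf,
    n_modes = cnt,
    n_frames = nf
  )
  class(out) <- c("fluctuation_spectrum", class(out))
  out
}

# Mid-surface height fields from headgroup positions: per-leaflet truncated
# Fourier fits evaluated on a regular mesh and averaged, per frame.
midsurface_fields <- function(frames, topo, n_grid = 16) {
  leaf <- assign_leaflets(frames, topo)
  gx <- (seq_len(n_grid) - 1) / n_grid
  mesh <- expand.grid(x = gx, y = gx)
  flist <- purrr::map(seq_len(frames$n_frames), function(f) {
    xyz <- frames$coords[[f]]; box <- frames$box[f, ]
    lf <- leaf$leaflet[leaf$frame == f]
    fit_leaflet <- function(which_leaf) {
      ha <- topo$headgroup_atoms[lf == which_leaf]
      pts <- cbind(xyz[ha, 1], xyz[ha, 2], xyz[ha, 3])
      hf <- fit_height_field(pts, box[1], box[2])
      matrix(eval_height_field(hf, mesh$x * box[1], mesh$y * box[2], "h"),
             n_grid, n_grid)
    }
    up <- fit_leaflet("upper"); lo <- fit_leaflet("lower")
    mid <- (up + lo) / 2
    mid - mean(mid)
  })
  structure(list(fields = flist, Lx = frames$box[1, 1], Ly = frames$box[1, 2],
                 n_grid = n_grid, temperature = NA_real_),
            class = "height_fields")
}

#' Bending modulus from the height-fluctuation spectrum
#'
#' Weighted nonlinear fit of `1/(KC q^4 + chi_s q^2)` (kBT energy units) to
#' the ensemble spectrum over modes with `q < q_cut`. The spectral tilt
#' term `chi_s` is reported separately from the molecular tilt modulus of
#' [tilt_modulus()]; the two are never conflated.
#'
#' @param x a `height_fields` object, a `fluctuation_spectrum`, or a
#'   [frame_ensemble()] (then `topo` is required and per-leaflet surfaces
#'   are fitted and averaged into a mid-surface field first)
#' @param topo a [chain_topology()] when `x` is a frame ensemble
#' @param q_cut fit only modes below this wavevector (1/nm); default
#'   `2*pi/1.5` excludes protrusion-dominated short wavelengths
#' @param fix_chi fix `chi_s` at this value instead of fitting it (use 0
#'   for a pure bending fit)
#' @param n_grid mesh used when fitting surfaces from a frame ensemble
#' @return an object of class `spectrum_fit`: `kc` (kBT), `kc_se`, `chi_s`
#'   (kBT/nm^2), `chi_s_se`, `q_cut`, `n_modes`, `r_squared`, `spectrum`
#' @export
bending_modulus_spectrum <- function(x, topo = NULL, q_cut = 2 * pi / 1.5,
                                     fix_chi = NULL, n_grid = 16) {
  spec <- if (inherits(x, "fluctuation_spectrum")) x
  else if (inherits(x, "height_fields")) height_spectrum(x)
  else if (inherits(x, "frame_ensemble")) {
    if (is.null(topo)) stop("topo required with a frame ensemble", call. = FALSE)
    height_spectrum(midsurface_fields(x, topo, n_grid))
  } else stop("unsupported input for bending_modulus_spectrum", call. = FALSE)

  d <- spec[spec$q < q_cut & spec$q > 0 & spec$h2 > 0, ]
  if (nrow(d) < 3) stop("fewer than 3 usable q shells below q_cut", call. = FALSE)
  if (all(!is.finite(d$se))) d$se <- d$h2  # single frame: relative weighting
  w <- 1 / pmax(d$se, max(d$se[d$se > 0], na.rm = TRUE) * 1e-6)^2
  kc0 <- stats::median(1 / (d$h2 * d$q^4))
  if (!is.null(fix_chi)) {
    chi0 <- fix_chi
    fit <- minpack.lm::nlsLM(
      h2 ~ 1 / (kc * q^4 + chi0 * q^2), data = d, weights = w,
      start = list(kc = kc0), lower = 0,
      control = minpack.lm::nls.lm.control(maxiter = 200))
    kc <- stats::coef(fit)[["kc"]]
    kc_se <- summary(fit)$coefficients["kc", 2]
    chi_s <- fix_chi; chi_se <- 0
  } else {
    fit <- minpack.lm::nlsLM(
      h2 ~ 1 / (kc * q^4 + chi * q^2), data = d, weights = w,
      start = list(kc = kc0, chi = 0.1), lower = c(0, 0),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    co <- summary(fit)$coefficients
    kc <- stats::coef(fit)[["kc"]]; kc_se <- co["kc", 2]
    chi_s <- stats::coef(fit)[["chi"]]; chi_se <- co["chi", 2]
  }
  pred <- stats::predict(fit)
  ss_res <- sum(w * (d$h2 - pred)^2)
  ss_tot <- sum(w * (d$h2 - stats::weighted.mean(d$h2, w))^2)
  structure(list(kc = kc, kc_se = kc_se, chi_s = chi_s, chi_s_se = chi_se,
                 q_cut = q_cut, n_modes = nrow(d),
                 n_frames = spec$n_frames[1],
                 r_squared = 1 - ss_res / ss_tot, spectrum = spec),
            class = "spectrum_fit")
}

#' @export
print.spectrum_fit <- function(x, ...) {
  cat(sprintf(
    "KC = %.2f +/- %.2f kBT; chi_s = %.2f +/- %.2f kBT/nm^2 (%d shells < q_cut %.2f, R^2 = %.3f)\n",
    x$kc, x$kc_se, x$chi_s, x$chi_s_se, x$n_modes, x$q_cut, x$r_squared))
  invisible(x)
}

# --- Helfrich bending energy -------------------------------------------------

#' Helfrich bending energy of a fitted height field
#'
#' `E_bend = (KC/2) * integral (c1 + c2)^2 dA` over one periodic cell, with
#' the total curvature evaluated from the analytic surface: small-slope
#' `c1 + c2 = lap h` by default, or the full Monge-gauge expression. The
#' integral uses tensor-product Gauss-Legendre quadrature; a refinement
#' check doubles the rule and warns when the result moves by more than 1%.
#'
#' @param height a `height_field_fit`
#' @param KC bending modulus; kBT units by default (converted with
#'   `temperature`)
#' @param temperature K, used to express the result in kJ/mol
#' @param curvature `"small_slope"` or `"monge"`
#' @param n_quad quadrature points per axis
#' @param refine_check verify against a doubled rule
#' @return bending energy in kJ/mol (numeric scalar) with attribute
#'   `diagnostics`
#' @export
bending_energy <- function(height, KC, temperature = 298,
                           curvature = c("small_slope", "monge"),
                           n_quad = 32, refine_check = TRUE) {
  stopifnot(inherits(height, "height_field_fit"))
  if (KC <= 0) stop("KC must be positive", call. = FALSE)
  curvature <- match.arg(curvature)
  quad <- function(n) {
    gx <- pracma::gaussLegendre(n, 0, height$Lx)
    gy <- pracma::gaussLegendre(n, 0, height$Ly)
    grid <- expand.grid(x = gx$x, y = gy$x)
    wts <- as.numeric(outer(gx$w, gy$w))
    if (curvature == "small_slope") {
      tc <- eval_height_field(height, grid$x, grid$y, "lap")
      sum(wts * tc^2)
    } else {
      g <- eval_height_field(height, grid$x, grid$y, "grad")
      hss <- eval_height_field(height, grid$x, grid$y, "hess")
      denom <- (1 + g$hx^2 + g$hy^2)
      tc <- ((1 + g$hy^2) * hss$hxx - 2 * g$hx * g$hy * hss$hxy +
               (1 + g$hx^2) * hss$hyy) / denom^1.5
      sum(wts * tc^2 * sqrt(denom))  # dA = sqrt(1+|grad h|^2) dx dy
    }
  }
  I <- quad(n_quad)
  if (refine_check) {
    I2 <- quad(2 * n_quad)
    if (I > 0 && abs(I2 - I) / max(I, 1e-300) > 0.01) {
      warning(sprintf(
        "bending-energy quadrature not converged: %.6g (n=%d) vs %.6g (n=%d)",
        I, n_quad, I2, 2 * n_quad), call. = FALSE)
    }
    I <- I2
  }
  kc_kJ <- KC * kBT_kJmol(temperature)
  e <- kc_kJ / 2 * I
  attr(e, "diagnostics") <- list(curvature = curvature, n_quad = n_quad,
                                 KC_kBT = KC, temperature = temperature)
  e
}

#' Bending-energy profile along the permeation coordinate
#'
#' For windowed ensembles keyed by the permeant depth z, averages the
#' Helfrich bending energy of each frame's fitted surface and reports it
#' against z, with the flat-reference energy (zero by construction of the
#' quadratic form) subtracted. Windows with fewer than 10 frames are
#' flagged.
#'
#' @param windows a named list: name = permeant z in nm, value = a
#'   `height_fields` object whose frames sample that window
#' @param KC bending modulus, kBT units
#' @param temperature K
#' @param ... passed to [bending_energy()]
#' @return a tibble of class `bending_profile`: `z`, `e_bend` (kJ/mol),
#'   `se`, `n_frames`, `flagged`
#' @export
bending_profile <- function(windows, KC, temperature = 298, ...) {
  stopifnot(is.list(windows), !is.null(names(windows)))
  rows <- purrr::imap(windows, function(hf, zname) {
    stopifnot(inherits(hf, "height_fields"))
    gx <- (seq_len(hf$n_grid) - 1) / hf$n_grid * hf$Lx
    gy <- (seq_len(hf$n_grid) - 1) / hf$n_grid * hf$Ly
    mesh <- expand.grid(x = gx, y = gy)
    es <- vapply(hf$fields, function(h) {
      fit <- fit_height_field(cbind(mesh$x, mesh$y, as.numeric(h)),
                              hf$Lx, hf$Ly)
      as.numeric(bending_energy(fit, KC, temperature, refine_check = FALSE, ...))
    }, numeric(1))
    tibble::tibble(z = as.numeric(zname), e_bend = mean(es),
                   se = stats::sd(es) / sqrt(length(es)),
                   n_frames = length(es), flagged = length(es) < 10)
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$z)
  class(out) <- c("bending_profile", class(out))
  out
}
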