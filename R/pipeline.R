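#' Config-driven pipeline runs and the synthetic end-to-end demo
#'
#' `run_pipeline()` executes the requested analyses in dependency order
#' from a YAML/list configuration and writes CSV profiles plus a JSON
#' results manifest; `demo_synthetic()` generates every synthetic fixture,
#' runs the full pipeline and emits a recovery table comparing each
#' estimate against the generator's ground truth.
#'
#' @name pipeline
NULL

#' Default pipeline configuration
#'
#' Every estimator parameter has a default matching the package's
#' documented conventions (0.05 nm cavity grid, spectrum fit below
#' `q = 2*pi/1.5` 1/nm, 10% burn-in, 5 blocks, 298 K).
#'
#' @return a nested list; see the fields in the source
#' @export
default_config <- function() {
  list(
    temperature = 298,
    seed = 1,
    outdir = ".",
    structure = NULL,    # list(path=, format="auto")
    trajectory = NULL,   # list(path=, format="text", stride=1)
    topology = NULL,     # sidecar path
    areas = NULL,        # list(path=, n_per_leaflet=64)
    forces = NULL,       # list(manifest=) : YAML list of {file, z, replicate}
    analyses = character(0),
    params = list(gridsize = 0.05, q_cut = 2 * pi / 1.5, burn_in = 0.1,
                  n_blocks = 5, n_bins = 72, n_grid = 16)
  )
}

#' Read a pipeline configuration
#'
#' @param path YAML config file
#' @return config list merged over [default_config()]
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(), user)
  cfg
}

load_force_windows <- function(forces_cfg, temperature, base_dir = ".") {
  man_path <- forces_cfg$manifest
  if (!file.exists(man_path)) {
    man_path <- file.path(base_dir, forces_cfg$manifest)
  }
  man <- yaml::read_yaml(man_path)
  purrr::map(man, function(entry) {
    fp <- entry$file
    if (!file.exists(fp)) fp <- file.path(dirname(man_path), entry$file)
    ts <- read_timeseries(fp)
    # last column is the force; first column is time when there are >= 2
    fcol <- ts[[ncol(ts)]]
    dt <- if (ncol(ts) >= 2) {
      tv <- ts[[1]]
      if (length(tv) > 1) tv[2] - tv[1] else 1
    } else 1
    force_window(z = entry$z, forces = fcol, dt = dt,
                 temperature = temperature,
                 replicate = entry$replicate %||% 1)
  })
}

stage_deps <- list(
  scd = character(0), gauche = character(0), cavity = character(0),
  phase = c("scd", "gauche"),
  ka = character(0), tilt = character(0), kc_spectrum = character(0),
  ti = character(0), diffusivity = character(0),
  resistance = c("ti", "diffusivity"),
  permeability = c("resistance")
)

#' Run the analysis pipeline from a configuration
#'
#' Stages run in dependency order (structure, mechanics, permeation); a
#' failed stage aborts its dependents but not independent stages. Every
#' output is a CSV (profiles) or JSON (scalars); the returned manifest
#' records file paths, the parameter echo, package version, wall time and
#' any warnings, and is itself written as `manifest.json`.
#'
#' @param config a config list (see [default_config()]) or a YAML path
#' @return an object of class `results_manifest`
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  cfg <- utils::modifyList(default_config(), config)
  t0 <- Sys.time()
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  requested <- cfg$analyses
  unknown <- setdiff(requested, names(stage_deps))
  if (length(unknown) > 0) stop("unknown analyses: ",
                                paste(unknown, collapse = ", "), call. = FALSE)
  # dependency-complete, dependency-ordered
  ordered <- intersect(names(stage_deps), requested)
  results <- list(); outputs <- list(); failed <- character(0)
  warns <- character(0)
  note <- function(...) warns <<- c(warns, sprintf(...))

  need_frames <- any(c("scd", "gauche", "cavity", "tilt", "kc_spectrum") %in%
                       ordered)
  frames <- NULL; topo <- NULL
  if (need_frames) {
    if (is.null(cfg$trajectory) && is.null(cfg$structure)) {
      stop("analyses ", paste(intersect(ordered, c("scd", "gauche", "cavity",
           "tilt", "kc_spectrum")), collapse = ", "),
           " need a trajectory or structure input", call. = FALSE)
    }
    frames <- if (!is.null(cfg$trajectory)) {
      read_trajectory(cfg$trajectory$path,
                      format = cfg$trajectory$format %||% "text",
                      stride = cfg$trajectory$stride %||% 1)
    } else {
      read_structure(cfg$structure$path, cfg$structure$format %||% "auto")$frames
    }
    if (is.null(cfg$topology)) {
      stop("structural analyses need a topology sidecar", call. = FALSE)
    }
    topo <- read_topology(cfg$topology)
  }

  run_stage <- function(stage, fun) {
    deps <- stage_deps[[stage]]
    if (any(deps %in% failed)) {
      failed <<- c(failed, stage)
      note("stage %s skipped: dependency failed (%s)", stage,
           paste(intersect(deps, failed), collapse = ", "))
      return(invisible(NULL))
    }
    res <- tryCatch(fun(), error = function(e) {
      failed <<- c(failed, stage)
      note("stage %s failed: %s", stage, conditionMessage(e))
      NULL
    })
    if (!is.null(res)) results[[stage]] <<- res
    invisible(NULL)
  }
  save_csv <- function(stage, obj) {
    p <- file.path(cfg$outdir, paste0(stage, ".csv"))
    write_profile_csv(obj, p)
    outputs[[stage]] <<- p
  }
  save_json <- function(stage, obj) {
    p <- file.path(cfg$outdir, paste0(stage, ".json"))
    jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA)
    outputs[[stage]] <<- p
  }

  for (stage in ordered) {
    switch(stage,
      scd = run_stage("scd", function() {
        r <- deuterium_order(frames, topo, n_blocks = cfg$params$n_blocks)
        save_csv("scd", r); r
      }),
      gauche = run_stage("gauche", function() {
        r <- gauche_fraction(frames, topo, n_blocks = cfg$params$n_blocks)
        save_csv("gauche", r); r
      }),
      cavity = run_stage("cavity", function() {
        r <- cavity_density(frames, topo, gridsize = cfg$params$gridsize)
        save_csv("cavity", r); r
      }),
      phase = run_stage("phase", function() {
        r <- classify_phase(results$scd, results$gauche,
                            KA = results$ka$KA %||% NULL,
                            chi = results$tilt$chi %||% NULL)
        save_json("phase", list(verdict = r$verdict,
                                evidence = as.data.frame(r$evidence)))
        r
      }),
      ka = run_stage("ka", function() {
        areas <- read_timeseries(cfg$areas$path)
        ser <- tibble::tibble(area_per_mol = areas[[ncol(areas)]])
        r <- area_compressibility(ser, temperature = cfg$temperature,
                                  N = cfg$areas$n_per_leaflet %||% 64,
                                  n_blocks = cfg$params$n_blocks)
        save_json("ka", list(KA_mNm = r$KA, se = r$se, n_frames = r$n_frames))
        r
      }),
      tilt = run_stage("tilt", function() {
        r <- tilt_modulus(frames, topo, n_bins = cfg$params$n_bins)
        save_json("tilt", list(chi_kBT_rad2 = r$chi, se = r$se,
                               alpha0_rad = r$alpha0, r_squared = r$r_squared))
        r
      }),
      kc_spectrum = run_stage("kc_spectrum", function() {
        r <- bending_modulus_spectrum(frames, topo, q_cut = cfg$params$q_cut,
                                      n_grid = cfg$params$n_grid)
        save_csv("kc_spectrum", r$spectrum)
        save_json("kc", list(KC_kBT = r$kc, se = r$kc_se,
                             chi_spectral = r$chi_s, r_squared = r$r_squared))
        r
      }),
      ti = run_stage("ti", function() {
        ws <- load_force_windows(cfg$forces, cfg$temperature, cfg$outdir)
        r <- free_energy_TI(ws, burn_in = cfg$params$burn_in)
        attr(r, "windows") <- ws
        save_csv("ti", r); r
      }),
      diffusivity = run_stage("diffusivity", function() {
        ws <- if (!is.null(results$ti)) attr(results$ti, "windows") else
          load_force_windows(cfg$forces, cfg$temperature, cfg$outdir)
        r <- diffusivity_profile(ws, burn_in = cfg$params$burn_in)
        save_csv("diffusivity", r); r
      }),
      resistance = run_stage("resistance", function() {
        r <- resistance_profile(results$ti, results$diffusivity,
                                temperature = cfg$temperature)
        save_csv("resistance", r); r
      }),
      permeability = run_stage("permeability", function() {
        r <- permeability(results$resistance)
        save_json("permeability", list(P_cm_s = r$P, se = r$se,
                                       R_total_s_cm = r$R_total,
                                       bounds_nm = r$bounds,
                                       z_max_resistance = r$z_max_resistance))
        r
      }))
  }

  manifest <- structure(list(
    outputs = outputs,
    analyses_requested = requested,
    analyses_failed = failed,
    parameters = cfg$params,
    temperature = cfg$temperature,
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("memperm")),
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    warnings = warns
  ), class = "results_manifest")
  jsonlite::write_json(unclass(manifest)[setdiff(names(manifest), "wall_time_s")],
                       file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$results <- results
  manifest
}

#' @export
print.results_manifest <- function(x, ...) {
  cat(sprintf("<results_manifest> %d outputs, %d failed stage(s), %.1f s\n",
              length(x$outputs), length(x$analyses_failed), x$wall_time_s))
  for (nm in names(x$outputs)) cat("  ", nm, "->", x$outputs[[nm]], "\n")
  if (length(x$warnings)) cat("warnings:\n ", paste(x$warnings, collapse = "\n  "), "\n")
  invisible(x)
}

#' Synthetic end-to-end demonstration with recovery table
#'
#' Generates every synthetic fixture at its reference conditions (order
#' target 0.45, gauche probability 0.10, KA 700 mN/m, tilt modulus 13
#' kBT/rad^2, bending modulus 20 kBT, a 30 kJ/mol Gaussian permeation
#' barrier), runs the corresponding estimator on each, and reports a
#' recovery table; the table is the package's living acceptance check.
#'
#' @param seed integer seed driving every generator
#' @param outdir optional output directory for CSVs and the manifest
#' @param n_surface_frames surfaces in the spectrum fixture
#' @return an object of class `demo_result`: `recovery` tibble (quantity,
#'   truth, estimate, tolerance, pass) plus the individual results
#' @export
demo_synthetic <- function(seed = 1, outdir = NULL, n_surface_frames = 800) {
  rows <- list(); res <- list()
  add <- function(quantity, truth, estimate, tolerance, kind) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      quantity = quantity, truth = truth, estimate = estimate,
      tolerance = tolerance, kind = kind,
      pass = switch(kind,
        relative = abs(estimate - truth) <= tolerance * abs(truth),
        absolute = abs(estimate - truth) <= tolerance,
        log = abs(log(estimate / truth)) <= tolerance)
    )
  }

  # chain order + gauche
  chain <- generate_chain_frames(chain_spec(
    n_chains = 400, n_carbons = 16, order_param_target = 0.45,
    gauche_prob = 0.10, seed = seed))
  scd <- deuterium_order(chain$frames, chain$topology)
  pl <- scd$abs_scd[scd$carbon %in% 4:12]
  add("plateau |SCD|", 0.45, mean(pl), 0.02, "absolute")
  g <- gauche_fraction(chain$frames, chain$topology)
  gt <- attr(chain, "ground_truth")
  nsamp <- sum(g$n_samples)
  add("gauche fraction", gt$gauche_fraction_realized,
      stats::weighted.mean(g$gauche, g$n_samples),
      3 * sqrt(0.1 * 0.9 / nsamp), "absolute")
  res$scd <- scd; res$gauche <- g

  # area compressibility
  areas <- generate_area_series(0.6, 700, N = 64, n_frames = 10000,
                                seed = seed + 1)
  ka <- area_compressibility(areas)
  add("KA (mN/m)", 700, ka$KA, 0.05, "relative")
  res$ka <- ka

  # tilt modulus
  ang <- sample_tilt_angles(20000, chi = 13, alpha0 = 0.3, seed = seed + 2)
  tf <- tilt_modulus(ang)
  add("tilt chi (kBT/rad^2)", 13, tf$chi, 0.10, "relative")
  res$tilt <- tf

  # bending modulus from the fluctuation spectrum
  surf <- generate_height_frames(surface_spec(
    Lx = 25, Ly = 25, n_grid = 16, KC_true = 20, chi_true = 0,
    n_frames = n_surface_frames, seed = seed + 3))
  sf <- bending_modulus_spectrum(surf)
  add("KC (kBT)", 20, sf$kc, 0.10, "relative")
  res$kc <- sf

  # permeation: 30 kJ/mol Gaussian barrier sampled at the 0.2 nm window grid,
  # 10 replicate 500 ps windows each (0.05 ps sampling)
  barrier <- 30; b_center <- 1.0; b_width <- 0.4; dz_win <- 0.2
  spec <- force_spec(
    z_values = seq(0, 2.8, by = dz_win),
    mean_force_profile = gaussian_barrier_force(barrier, b_center, b_width),
    force_variance = 400, correlation_time = 0.5, dt = 0.05,
    n_steps = 10000, temperature = 298, n_replicates = 10, seed = seed + 4)
  ws <- generate_force_windows(spec)
  pipe <- permeation_pipeline(ws)
  gt_f <- attr(ws, "ground_truth")
  # composite-trapezoid bound on the TI discretization error at the peak
  eps_trap <- dz_win^2 / 12 * barrier / b_width^2
  add("TI barrier (kJ/mol)", max(gt_f$dG$dG), max(pipe$free_energy$dG),
      eps_trap + 1, "absolute")
  add("local D (nm^2/ps)", gt_f$D, mean(pipe$diffusivity$D_nm2ps), 0.15,
      "relative")
  # the TI discretization error enters P exponentially: bound on the log scale
  P_true <- analytic_permeability(gaussian_dG(barrier, b_center, b_width),
                                  gt_f$D, 2.8, temperature = 298)
  add("permeability (cm/s)", P_true, pipe$permeability$P,
      eps_trap / kBT_kJmol(298) + log(1.2), "log")
  res$permeation <- pipe

  recovery <- dplyr::bind_rows(rows)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_profile_csv(scd, file.path(outdir, "scd.csv"))
    write_profile_csv(g, file.path(outdir, "gauche.csv"))
    write_profile_csv(sf$spectrum, file.path(outdir, "spectrum.csv"))
    write_profile_csv(pipe$free_energy, file.path(outdir, "free_energy.csv"))
    write_profile_csv(pipe$diffusivity, file.path(outdir, "diffusivity.csv"))
    write_profile_csv(pipe$resistance, file.path(outdir, "resistance.csv"))
    write_profile_csv(recovery, file.path(outdir, "recovery.csv"))
    jsonlite::write_json(
      list(seed = seed,
           package_version = as.character(utils::packageVersion("memperm")),
           recovery = as.data.frame(recovery)),
      file.path(outdir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  structure(list(recovery = recovery, results = res, seed = seed),
            class = "demo_result")
}

#' @export
print.demo_result <- function(x, ...) {
  cat("Synthetic end-to-end recovery (seed", x$seed, ")\n")
  print(as.data.frame(x$recovery), row.names = FALSE, digits = 4)
  invisible(x)
}

# --- analytic helpers shared by the demo and the tests -----------------------

#' Gaussian free-energy barrier and its force
#'
#' `gaussian_dG(height, center, width)` returns the free-energy function
#' `G(z) = height * exp(-(z - center)^2 / (2 width^2))` (kJ/mol);
#' `gaussian_barrier_force()` returns the corresponding mean force on the
#' permeant `f(z) = -dG/dz`, so thermodynamic integration from bulk inward
#' recovers `G`.
#'
#' @param height barrier height, kJ/mol
#' @param center barrier position, nm
#' @param width Gaussian sigma, nm
#' @return a function of z
#' @export
gaussian_dG <- function(height, center, width) {
  function(z) height * exp(-(z - center)^2 / (2 * width^2))
}

#' @rdname gaussian_dG
#' @export
gaussian_barrier_force <- function(height, center, width) {
  function(z) height * (z - center) / width^2 * exp(-(z - center)^2 / (2 * width^2))
}

#' Sample tilt angles from a quadratic tilt free energy
#'
#' Inverse of the Boltzmann-inversion estimator: draws alpha from
#' `P(alpha) proportional to sin(alpha) exp(-(chi/2)(alpha - alpha0)^2)` by
#' rejection, the distribution whose inverted free energy is quadratic with
#' curvature chi.
#'
#' @param n samples
#' @param chi tilt modulus, kBT/rad^2 (0 = uniform on the hemisphere)
#' @param alpha0 equilibrium tilt, rad
#' @param seed integer seed
#' @return numeric vector of angles in `[0, pi/2]`, rad
#' @export
sample_tilt_angles <- function(n, chi, alpha0 = 0, seed = 1) {
  with_local_seed(seed, {
    out <- numeric(0)
    dens <- function(a) sin(a) * exp(-chi / 2 * (a - alpha0)^2)
    amax <- stats::optimize(dens, c(0, pi / 2), maximum = TRUE)$objective
    while (length(out) < n) {
      m <- max(64L, 2L * (n - length(out)))
      a <- stats::runif(m, 0, pi / 2)
      acc <- stats::runif(m) < dens(a) / amax
      out <- c(out, a[acc])
    }
    out[seq_len(n)]
  })
}

#' Analytic permeability for a known free-energy and diffusivity profile
#'
#' Quadrature reference for the solubility-diffusivity inversion:
#' `1/P = integral exp(dG(z)/kBT)/D dz` over the mirrored membrane
#' `[-z_max, z_max]`, evaluated with adaptive quadrature rather than the
#' pipeline's trapezoid grid.
#'
#' @param dG function of z, kJ/mol
#' @param D constant diffusivity, nm^2/ps (or function of z)
#' @param z_max half-thickness, nm
#' @param temperature K
#' @return permeability in cm/s
#' @export
analytic_permeability <- function(dG, D, z_max, temperature = 298) {
  kT <- kBT_kJmol(temperature)
  Dfun <- if (is.function(D)) D else function(z) rep(D, length(z))
  integrand <- function(z) exp(dG(abs(z)) / kT) / Dfun(abs(z))
  R <- stats::integrate(integrand, -z_max, z_max, rel.tol = 1e-9)$value
  (1 / R) * .nmps_to_cms
}
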