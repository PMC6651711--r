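#' Structure, trajectory and time-series readers
#'
#' All coordinates are converted to nm on input regardless of the source
#' format (PDB records are in Angstrom and are divided by 10). Internally the
#' package works exclusively in nm / ps / kJ-per-mol.
#'
#' @name io
NULL

#' Read a single-frame structure file
#'
#' Supports GROMACS GRO (nm, fixed-width) and PDB (Angstrom, converted;
#' the box is taken from the CRYST1 record).
#'
#' @param path path to the structure file
#' @param format `"gro"` or `"pdb"`; guessed from the file extension when
#'   omitted
#' @return a list with `frames` (a single-frame [frame_ensemble()]) and
#'   `atoms` (a tibble of atom metadata: resid, resname, name, index)
#' @export
read_structure <- function(path, format = c("auto", "gro", "pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     gro = "gro", pdb = "pdb",
                     stop("cannot guess structure format from extension: ", path,
                          call. = FALSE))
  }
  switch(format, gro = read_gro(path), pdb = read_pdb_nm(path))
}

read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("GRO file too short: ", path, call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) stop("GRO parse error at line 2: atom count expected", call. = FALSE)
  if (length(lines) < 2 + n + 1) {
    stop("GRO file truncated: expected ", n, " atom lines", call. = FALSE)
  }
  atom_lines <- lines[3:(2 + n)]
  parse_num <- function(s, what, i) {
    v <- suppressWarnings(as.numeric(s))
    if (any(is.na(v))) {
      stop("GRO parse error at line ", 2 + i, ": bad ", what, call. = FALSE)
    }
    v
  }
  resid <- integer(n); resname <- character(n); name <- character(n)
  xyz <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    ln <- atom_lines[i]
    if (nchar(ln) < 44) stop("GRO parse error at line ", 2 + i, ": record too short",
                             call. = FALSE)
    resid[i] <- as.integer(parse_num(substr(ln, 1, 5), "resid", i))
    resname[i] <- trimws(substr(ln, 6, 10))
    name[i] <- trimws(substr(ln, 11, 15))
    xyz[i, 1] <- parse_num(substr(ln, 21, 28), "x", i)
    xyz[i, 2] <- parse_num(substr(ln, 29, 36), "y", i)
    xyz[i, 3] <- parse_num(substr(ln, 37, 44), "z", i)
  }
  box_fields <- strsplit(trimws(lines[2 + n + 1]), "\\s+")[[1]]
  if (length(box_fields) < 3) {
    stop("GRO file missing box record on last line", call. = FALSE)
  }
  box <- suppressWarnings(as.numeric(box_fields[1:3]))
  if (any(is.na(box)) || any(box <= 0)) {
    stop("GRO box record invalid: ", lines[2 + n + 1], call. = FALSE)
  }
  list(
    frames = frame_ensemble(list(xyz), box),
    atoms = tibble::tibble(index = seq_len(n), resid = resid,
                           resname = resname, name = name)
  )
}

read_pdb_nm <- function(path) {
  pdb <- bio3d::read.pdb(path)
  xyz <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE) / 10  # A -> nm
  cryst <- grep("^CRYST1", readLines(path), value = TRUE)
  if (length(cryst) == 0) {
    stop("PDB file has no CRYST1 record; box required", call. = FALSE)
  }
  box <- as.numeric(c(substr(cryst[1], 7, 15), substr(cryst[1], 16, 24),
                      substr(cryst[1], 25, 33))) / 10
  if (any(is.na(box)) || any(box <= 0)) {
    stop("PDB CRYST1 record invalid", call. = FALSE)
  }
  list(
    frames = frame_ensemble(list(xyz), box),
    atoms = tibble::tibble(index = seq_len(nrow(xyz)),
                           resid = pdb$atom$resno,
                           resname = pdb$atom$resid,
                           name = pdb$atom$elety)
  )
}

#' Write a single frame to a GRO file
#'
#' @param frames a [frame_ensemble()]; the first frame is written
#' @param path output path
#' @param atoms optional atom metadata tibble (as from [read_structure()]);
#'   generic names are generated when omitted
#' @param frame which frame to write
#' @return `path`, invisibly
#' @export
write_gro <- function(frames, path, atoms = NULL, frame = 1) {
  stopifnot(inherits(frames, "frame_ensemble"))
  xyz <- frames$coords[[frame]]
  n <- nrow(xyz)
  if (is.null(atoms)) {
    atoms <- tibble::tibble(index = seq_len(n), resid = seq_len(n),
                            resname = "MOL", name = "C")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("memperm frame", sprintf("%5d", n)), con)
  writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     atoms$resid %% 100000, substr(atoms$resname, 1, 5),
                     substr(atoms$name, 1, 5), atoms$index %% 100000,
                     xyz[, 1], xyz[, 2], xyz[, 3]), con)
  writeLines(sprintf("%10.5f%10.5f%10.5f", frames$box[frame, 1],
                     frames$box[frame, 2], frames$box[frame, 3]), con)
  invisible(path)
}

#' Read a trajectory
#'
#' Formats: `"text"`, the package's plain multi-frame format (see
#' [write_trajectory()]); `"dcd"`, read through bio3d (coordinates assumed
#' Angstrom and converted to nm). XTC is not supported.
#'
#' @param path trajectory file
#' @param format `"text"` or `"dcd"`
#' @param topology optional [chain_topology()]; when given, the atom count is
#'   checked against it
#' @param stride keep every `stride`-th frame
#' @param n_atoms expected atom count (alternative to `topology`)
#' @return a [frame_ensemble()]
#' @export
read_trajectory <- function(path, format = c("text", "dcd"), topology = NULL,
                            stride = 1, n_atoms = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  fr <- switch(format,
    text = read_trajectory_text(path),
    dcd = {
      dcd <- bio3d::read.dcd(path)
      coords <- purrr::map(seq_len(nrow(dcd)), function(i) {
        matrix(dcd[i, ], ncol = 3, byrow = TRUE) / 10
      })
      frame_ensemble(coords, box = c(1, 1, 1) * NA_real_)
    })
  expected <- if (!is.null(topology)) max(unlist(topology$chains)) else n_atoms
  if (!is.null(expected) && fr$n_atoms < expected) {
    stop("trajectory atom count (", fr$n_atoms,
         ") smaller than topology requires (", expected, ")", call. = FALSE)
  }
  if (stride > 1) {
    keep <- seq(1, fr$n_frames, by = stride)
    fr <- frame_ensemble(fr$coords[keep], fr$box[keep, , drop = FALSE],
                         fr$time[keep])
  }
  fr
}

read_trajectory_text <- function(path) {
  lines <- readLines(path)
  heads <- grep("^FRAME", lines)
  if (length(heads) == 0) stop("no FRAME records in ", path, call. = FALSE)
  coords <- list(); box <- NULL; time <- numeric(0)
  for (k in seq_along(heads)) {
    h <- heads[k]
    fields <- strsplit(trimws(lines[h]), "\\s+")[[1]]
    # FRAME <time_ps> <natoms> <lx> <ly> <lz>
    if (length(fields) < 6) stop("malformed FRAME header at line ", h, call. = FALSE)
    t <- as.numeric(fields[2]); n <- as.integer(fields[3])
    b <- as.numeric(fields[4:6])
    last <- if (k < length(heads)) heads[k + 1] - 1 else length(lines)
    body <- lines[(h + 1):last]
    body <- body[nzchar(trimws(body))]
    if (length(body) < n) {
      stop("truncated trajectory: frame ", k, " at line ", h,
           " has ", length(body), " of ", n, " atoms; last complete frame: ",
           k - 1, call. = FALSE)
    }
    m <- matrix(scan(text = body[seq_len(n)], quiet = TRUE), ncol = 3, byrow = TRUE)
    coords[[k]] <- m
    box <- rbind(box, b)
    time <- c(time, t)
  }
  frame_ensemble(coords, box, time)
}

#' Write a trajectory in the plain multi-frame text format
#'
#' Each frame is a `FRAME <time_ps> <n_atoms> <Lx> <Ly> <Lz>` header followed
#' by one `x y z` line per atom (nm). The format round-trips exactly at the
#' printed precision and is the package's text-only interchange format.
#'
#' @param frames a [frame_ensemble()]
#' @param path output path
#' @param digits printed significant digits
#' @return `path`, invisibly
#' @export
write_trajectory <- function(frames, path, digits = 8) {
  stopifnot(inherits(frames, "frame_ensemble"))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(frames$n_frames)) {
    writeLines(sprintf("FRAME %.6f %d %.8f %.8f %.8f", frames$time[f],
                       frames$n_atoms, frames$box[f, 1], frames$box[f, 2],
                       frames$box[f, 3]), con)
    xyz <- frames$coords[[f]]
    writeLines(sprintf(paste0("%.", digits, "f %.", digits, "f %.", digits, "f"),
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}

#' Read a numeric time series (XVG or CSV)
#'
#' XVG files in the Grace dialect (lines starting with `@` or `#` are
#' comments) yield columns `V1`, `V2`, ...; CSV files keep their header
#' names.
#'
#' @param path file path
#' @return a tibble of numeric columns
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) == 0 || all(!nzchar(trimws(lines)))) {
    stop("empty time-series file: ", path, call. = FALSE)
  }
  is_xvg <- grepl("\\.xvg$", path, ignore.case = TRUE) ||
    any(grepl("^[@#]", lines))
  if (is_xvg) {
    body <- lines[!grepl("^\\s*[@#]", lines)]
    body <- body[nzchar(trimws(body))]
    if (length(body) == 0) stop("time-series file has no data rows: ", path,
                                call. = FALSE)
    parts <- strsplit(trimws(body), "\\s+")
    ncols <- unique(lengths(parts))
    if (length(ncols) != 1) {
      stop("ragged rows in time-series file: ", path, call. = FALSE)
    }
    m <- matrix(as.numeric(unlist(parts)), ncol = ncols, byrow = TRUE)
    if (anyNA(m)) stop("non-numeric data in time-series file: ", path, call. = FALSE)
    tibble::as_tibble(as.data.frame(m))
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    if (nrow(df) == 0) stop("time-series file has no data rows: ", path, call. = FALSE)
    df
  }
}

#' Read a chain-topology sidecar (YAML or JSON)
#'
#' The sidecar lists `chains` (1-based atom indices, head to tail), and
#' optionally `ch_bonds` (pairs or `"reconstruct"`), `headgroup_atoms` and
#' `species`.
#'
#' @param path sidecar file
#' @return a [chain_topology()]
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(spec$chains)) stop("topology sidecar must define 'chains'", call. = FALSE)
  chains <- purrr::map(spec$chains, as.integer)
  ch_bonds <- spec$ch_bonds %||% "reconstruct"
  if (!identical(ch_bonds, "reconstruct")) {
    ch_bonds <- matrix(as.integer(unlist(ch_bonds)), ncol = 2, byrow = TRUE)
  }
  chain_topology(
    chains = chains, ch_bonds = ch_bonds,
    headgroup_atoms = if (!is.null(spec$headgroup_atoms))
      as.integer(spec$headgroup_atoms) else NULL,
    species = spec$species %||% NULL
  )
}

#' Write a z-profile tibble to CSV
#'
#' @param profile a tibble (any of the package's profile results)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_profile_csv <- function(profile, path) {
  readr::write_csv(tibble::as_tibble(profile), path, progress = FALSE)
  invisible(path)
}
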