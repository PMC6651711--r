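#' Frame ensembles and chain topologies
#'
#' A `frame_ensemble` holds per-frame particle coordinates together with the
#' (orthorhombic) box for each frame; it is the substrate of every structural
#' and mechanical estimator in the package. A `chain_topology` maps atoms to
#' alkyl chains: backbone order, C-H bond pairs (or a request to reconstruct
#' ideal hydrogens on united-atom chains), dihedral quadruples, leaflet labels
#' and the headgroup atoms that define the membrane surface.
#'
#' @name containers
NULL

#' Construct a frame ensemble
#'
#' @param coords a list of n_atoms x 3 numeric matrices (nm), one per frame,
#'   all with the same number of rows
#' @param box an n_frames x 3 matrix of box edge lengths (Lx, Ly, Lz) in nm,
#'   or a length-3 vector recycled to every frame
#' @param time per-frame times in ps (defaults to 0, 1, 2, ...)
#' @return an object of class `frame_ensemble`
#' @export
frame_ensemble <- function(coords, box, time = NULL) {
  if (is.matrix(coords)) coords <- list(coords)
  stopifnot(is.list(coords), length(coords) >= 1)
  n_atoms <- nrow(coords[[1]])
  ok <- vapply(coords, function(m) is.matrix(m) && ncol(m) == 3 && nrow(m) == n_atoms,
               logical(1))
  if (!all(ok)) {
    stop("all frames must be n_atoms x 3 matrices with a constant atom count",
         call. = FALSE)
  }
  n_frames <- length(coords)
  if (is.vector(box) && length(box) == 3) {
    box <- matrix(rep(box, each = n_frames), nrow = n_frames)
  }
  box <- as.matrix(box)
  stopifnot(nrow(box) == n_frames, ncol(box) == 3)
  if (any(box <= 0)) stop("box dimensions must be positive", call. = FALSE)
  if (is.null(time)) time <- seq_len(n_frames) - 1
  stopifnot(length(time) == n_frames)
  structure(
    list(coords = coords, box = box, time = as.numeric(time),
         n_frames = n_frames, n_atoms = n_atoms),
    class = "frame_ensemble"
  )
}

#' @export
print.frame_ensemble <- function(x, ...) {
  cat(sprintf("<frame_ensemble> %d frames, %d atoms, box[1] = (%.3f, %.3f, %.3f) nm\n",
              x$n_frames, x$n_atoms, x$box[1, 1], x$box[1, 2], x$box[1, 3]))
  invisible(x)
}

#' Construct a chain topology
#'
#' @param chains list of integer vectors: backbone carbon atom indices for
#'   each chain, ordered head to tail; every chain needs at least 4 carbons
#' @param ch_bonds either a two-column matrix/data.frame of (carbon, hydrogen)
#'   atom-index pairs, or the string `"reconstruct"` to place ideal-geometry
#'   hydrogens on each CH2/CH3 of a united-atom chain at analysis time
#' @param dihedrals optional list of 4-long integer vectors (consecutive
#'   backbone atoms); derived from `chains` when omitted
#' @param leaflet optional per-chain labels, `"upper"`/`"lower"`; computed
#'   per frame from headgroup z when omitted
#' @param headgroup_atoms optional integer vector of atom indices defining
#'   the membrane surface (defaults to the first carbon of each chain)
#' @param species optional per-chain species label (character)
#' @return an object of class `chain_topology`
#' @export
chain_topology <- function(chains, ch_bonds = "reconstruct", dihedrals = NULL,
                           leaflet = NULL, headgroup_atoms = NULL,
                           species = NULL) {
  stopifnot(is.list(chains), length(chains) >= 1)
  if (any(vapply(chains, length, integer(1)) < 4)) {
    stop("every chain must have at least 4 carbons", call. = FALSE)
  }
  if (is.null(dihedrals)) {
    dihedrals <- purrr::map(chains, function(ch) {
      if (length(ch) < 4) return(NULL)
      purrr::map(seq_len(length(ch) - 3), function(i) ch[i:(i + 3)])
    })
    dihedrals <- purrr::flatten(dihedrals)
  }
  bad <- purrr::map_lgl(dihedrals, function(d) length(d) != 4)
  if (any(bad)) stop("dihedral quadruples must have 4 atoms", call. = FALSE)
  if (!identical(ch_bonds, "reconstruct")) {
    ch_bonds <- as.matrix(ch_bonds)
    stopifnot(ncol(ch_bonds) == 2)
  }
  if (is.null(headgroup_atoms)) {
    headgroup_atoms <- vapply(chains, function(ch) ch[[1]], integer(1))
  }
  if (is.null(species)) species <- rep("chain", length(chains))
  stopifnot(length(species) == length(chains))
  structure(
    list(chains = chains, ch_bonds = ch_bonds, dihedrals = dihedrals,
         leaflet = leaflet, headgroup_atoms = as.integer(headgroup_atoms),
         species = as.character(species)),
    class = "chain_topology"
  )
}

#' @export
print.chain_topology <- function(x, ...) {
  cat(sprintf("<chain_topology> %d chains, %d dihedrals, ch_bonds: %s\n",
              length(x$chains), length(x$dihedrals),
              if (identical(x$ch_bonds, "reconstruct")) "reconstruct" else
                sprintf("%d pairs", nrow(x$ch_bonds))))
  invisible(x)
}

# Minimum-image displacement r2 - r1 for one orthorhombic box.
# Analyses that need whole molecules (chain vectors, dihedrals) call this on
# bonded pairs, so correctness does not depend on how the source wrapped
# coordinates.
min_image <- function(r1, r2, box) {
  d <- r2 - r1
  d - round(d / box) * box
}

#' Assign chains to leaflets by headgroup height
#'
#' A molecule belongs to the upper leaflet in a given frame when the z of its
#' headgroup atom exceeds the bilayer center of mass (mean z over all chain
#' atoms), recomputed per frame so the assignment is robust to drift.
#'
#' @param frames a [frame_ensemble()]
#' @param topo a [chain_topology()]
#' @return a tibble with columns `frame`, `chain`, `leaflet`
#' @export
assign_leaflets <- function(frames, topo) {
  stopifnot(inherits(frames, "frame_ensemble"), inherits(topo, "chain_topology"))
  all_atoms <- unique(unlist(topo$chains))
  purrr::map_dfr(seq_len(frames$n_frames), function(f) {
    z <- frames$coords[[f]][, 3]
    z0 <- mean(z[all_atoms])
    zh <- z[topo$headgroup_atoms]
    tibble::tibble(
      frame = f,
      chain = seq_along(topo$chains),
      leaflet = ifelse(zh > z0, "upper", "lower")
    )
  })
}

# Reconstruct ideal-geometry hydrogens on a united-atom backbone.
# For interior carbon C_i with neighbours C_{i-1}, C_{i+1}: the two H
# directions lie in the plane bisecting the backbone angle, tilted by half
# the tetrahedral H-C-H angle out of the backbone plane. Returns unit
# direction vectors (2 per interior carbon); terminal carbons are handled by
# the caller. C-H bond length 0.109 nm when positions are needed.
reconstruct_ch_directions <- function(cprev, c0, cnext, box) {
  up <- min_image(c0, cprev, box); up <- up / sqrt(sum(up^2))
  un <- min_image(c0, cnext, box); un <- un / sqrt(sum(un^2))
  b <- -(up + un)
  nb <- sqrt(sum(b^2))
  if (nb < 1e-10) stop("colinear backbone triplet; cannot place hydrogens", call. = FALSE)
  b <- b / nb
  pl <- pracma::cross(up, un)
  npl <- sqrt(sum(pl^2))
  if (npl < 1e-10) stop("colinear backbone triplet; cannot place hydrogens", call. = FALSE)
  pl <- pl / npl
  half <- 0.5 * 109.47 * pi / 180
  list(b * cos(half) + pl * sin(half),
       b * cos(half) - pl * sin(half))
}
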