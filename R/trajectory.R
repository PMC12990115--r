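#' Construct a trajectory frame set
#'
#' `md_frames` stores coordinates for a whole trajectory as an
#' `n_frames x 3*n_atoms` matrix in nm (bio3d xyz layout:
#' x1, y1, z1, x2, ...), with per-frame times in ps and an optional
#' orthorhombic box.
#'
#' @param xyz Numeric matrix, `n_frames` rows, `3 * n_atoms` columns (nm).
#' @param times Numeric vector of frame times (ps), non-negative,
#'   strictly increasing.
#' @param box Optional length-3 box vector (nm).
#' @return An object of class `md_frames`.
#' @export
md_frames <- function(xyz, times, box = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) %% 3L != 0L) stop("xyz must have 3*n_atoms columns")
  if (nrow(xyz) == 0L) stop("zero frames")
  times <- as.numeric(times)
  if (length(times) != nrow(xyz)) stop("times must match frame count")
  if (any(times < 0)) stop("frame times must be non-negative")
  if (nrow(xyz) > 1L && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  structure(list(xyz = xyz, times = times, n_atoms = ncol(xyz) %/% 3L,
                 box = box),
            class = "md_frames")
}

#' @export
print.md_frames <- function(x, ...) {
  cat(sprintf("<md_frames: %d frames x %d atoms, t = [%g, %g] ps>\n",
              nrow(x$xyz), x$n_atoms, min(x$times), max(x$times)))
  invisible(x)
}

#' @export
length.md_frames <- function(x) nrow(x$xyz)

#' Extract one frame as an n_atoms x 3 coordinate matrix (nm)
#'
#' @param frames An [md_frames] object.
#' @param i Frame index (1-based).
#' @return Numeric matrix with one row per atom, columns x/y/z (nm).
#' @export
frame_coords <- function(frames, i) {
  stopifnot(inherits(frames, "md_frames"))
  if (i < 1L || i > nrow(frames$xyz)) stop("frame index out of range")
  matrix(frames$xyz[i, ], ncol = 3L, byrow = TRUE)
}

#' Define the labeled atom groups of a fluorophore-tagged peptide
#'
#' Identifies the atoms the FRET observables are built from: the Trp
#' indole fusion bond and the Dbo diazo group (whose midpoints define
#' \eqn{R_{ee}}), the donor/acceptor transition-dipole atom pairs, and
#' the terminal C-alpha atoms. Indices are 1-based into the topology.
#'
#' @param indole_bond Integer pair: atoms of the Trp indole fusion bond.
#' @param diazo_group Integer pair: atoms of the Dbo diazo (N=N) group.
#' @param donor_dipole Integer pair defining the donor transition dipole.
#' @param acceptor_dipole Integer pair defining the acceptor dipole.
#' @param terminal_ca Integer pair: first and last residue C-alpha atoms.
#' @param heavy_atoms Integer vector of non-hydrogen atoms (clustering).
#' @param masses Numeric vector of atomic masses (u), one per atom.
#' @return An object of class `label_map`.
#' @export
label_map <- function(indole_bond, diazo_group, donor_dipole,
                      acceptor_dipole, terminal_ca, heavy_atoms, masses) {
  chk_pair <- function(p, nm) {
    p <- as.integer(p)
    if (length(p) != 2L || any(p < 1L)) stop(nm, " must be two valid indices")
    if (p[1L] == p[2L]) stop(nm, " is degenerate (identical atoms)")
    p
  }
  n <- length(masses)
  lm <- structure(list(indole_bond = chk_pair(indole_bond, "indole_bond"),
                       diazo_group = chk_pair(diazo_group, "diazo_group"),
                       donor_dipole = chk_pair(donor_dipole, "donor_dipole"),
                       acceptor_dipole = chk_pair(acceptor_dipole,
                                                  "acceptor_dipole"),
                       terminal_ca = chk_pair(terminal_ca, "terminal_ca"),
                       heavy_atoms = as.integer(heavy_atoms),
                       masses = as.numeric(masses)),
                  class = "label_map")
  idx <- c(lm$indole_bond, lm$diazo_group, lm$donor_dipole,
           lm$acceptor_dipole, lm$terminal_ca, lm$heavy_atoms)
  if (any(idx > n)) stop("label indices exceed atom count (", n, ")")
  if (any(lm$masses < 0)) stop("masses must be non-negative")
  lm
}

#' Read a trajectory into an md_frames object
#'
#' Supported inputs: a multi-model PDB (trajectory and topology in one
#' file) or a DCD trajectory with a PDB topology. Coordinates are
#' converted from Angstrom to nm on ingestion. Neither format carries
#' physical time, so frame times are assigned as `(0:(n-1)) * dt`.
#'
#' @param trajectory_path Path to a multi-model PDB or a DCD file.
#' @param topology_path Path to a PDB topology; required for DCD, ignored
#'   (may be `NULL`) for multi-model PDB input.
#' @param dt Frame spacing in ps (default 1).
#' @return An [md_frames] object.
#' @export
read_trajectory <- function(trajectory_path, topology_path = NULL, dt = 1) {
  if (!file.exists(trajectory_path))
    stop("unreadable trajectory file: ", trajectory_path)
  ext <- tolower(sub(".*\\.", "", trajectory_path))
  if (ext == "dcd") {
    if (is.null(topology_path) || !file.exists(topology_path))
      stop("DCD input requires an existing PDB topology")
    top <- bio3d::read.pdb(topology_path)
    xyz <- bio3d::read.dcd(trajectory_path, verbose = FALSE)
    if (ncol(xyz) != length(top$xyz))
      stop("atom-count mismatch between trajectory and topology")
  } else {
    pdb <- bio3d::read.pdb(trajectory_path, multi = TRUE)
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
    if (!is.null(topology_path) && file.exists(topology_path)) {
      top <- bio3d::read.pdb(topology_path)
      if (ncol(xyz) != length(top$xyz))
        stop("atom-count mismatch between trajectory and topology")
    }
  }
  if (nrow(xyz) == 0L || ncol(xyz) == 0L) stop("zero frames in trajectory")
  md_frames(xyz * 0.1, times = (seq_len(nrow(xyz)) - 1) * dt)
}

#' Write frames as a multi-model PDB
#'
#' Writes each frame as a MODEL record (nm converted back to Angstrom),
#' readable again with [read_trajectory()]. Atoms are emitted as generic
#' carbons; element identity is not used by any analysis here.
#'
#' @param frames An [md_frames] object.
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_frames_pdb <- function(frames, path) {
  stopifnot(inherits(frames, "md_frames"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(frames$xyz))) {
    co <- frame_coords(frames, i) * 10  # nm -> Angstrom
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(sprintf(
      "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(nrow(co)), seq_len(nrow(co)), co[, 1], co[, 2], co[, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

.midpoint <- function(co, pair) (co[pair[1L], ] + co[pair[2L], ]) / 2

#' Donor-acceptor end-to-end distance of one frame
#'
#' Euclidean distance between the midpoint of the Trp indole fusion bond
#' and the midpoint of the Dbo diazo group.
#'
#' @param coords n_atoms x 3 coordinate matrix (nm), e.g. from
#'   [frame_coords()].
#' @param labels A [label_map].
#' @return Distance in nm.
#' @export
end_to_end_distance <- function(coords, labels) {
  stopifnot(inherits(labels, "label_map"))
  sqrt(sum((.midpoint(coords, labels$indole_bond) -
            .midpoint(coords, labels$diazo_group))^2))
}

#' Terminal C-alpha to C-alpha distance of one frame
#'
#' @inheritParams end_to_end_distance
#' @return Distance in nm.
#' @export
ca_ca_distance <- function(coords, labels) {
  stopifnot(inherits(labels, "label_map"))
  p <- labels$terminal_ca
  sqrt(sum((coords[p[1L], ] - coords[p[2L], ])^2))
}

#' Mass-weighted radius of gyration of one frame
#'
#' @inheritParams end_to_end_distance
#' @return \eqn{R_g} in nm, about the center of mass.
#' @export
radius_of_gyration <- function(coords, labels) {
  stopifnot(inherits(labels, "label_map"))
  m <- labels$masses
  M <- sum(m)
  if (M <= 0) stop("zero total mass")
  com <- colSums(coords * m) / M
  d2 <- rowSums(sweep(coords, 2L, com)^2)
  sqrt(sum(m * d2) / M)
}

#' FRET orientational factor kappa-squared
#'
#' \eqn{\kappa^2 = (\cos\theta_T - 3 \cos\theta_D \cos\theta_A)^2} where
#' \eqn{\theta_D} and \eqn{\theta_A} are the angles between each
#' transition dipole and the end-to-end vector and \eqn{\theta_T} is the
#' angle between the two dipoles. Bounded in \eqn{[0, 4]}; the isotropic
#' dynamic average is 2/3.
#'
#' @param donor,acceptor,ree Unit 3-vectors: donor dipole, acceptor
#'   dipole, and the normalized end-to-end vector.
#' @param tol Tolerance on the unit-norm check.
#' @return \eqn{\kappa^2}, dimensionless in \eqn{[0, 4]}.
#' @examples
#' kappa_squared(c(0, 0, 1), c(0, 0, 1), c(0, 0, 1))  # collinear: 4
#' @export
kappa_squared <- function(donor, acceptor, ree, tol = 1e-6) {
  for (v in list(donor, acceptor, ree))
    if (abs(sum(v^2) - 1) > tol) stop("inputs must be unit vectors")
  ct <- sum(donor * acceptor)
  cd <- sum(donor * ree)
  ca <- sum(acceptor * ree)
  (ct - 3 * cd * ca)^2
}

#' Kappa-squared for whole series of dipole orientations
#'
#' Vectorized over a `dipole_series` (rows of unit vectors).
#'
#' @param dipoles A [dipole_series].
#' @return Numeric vector of \eqn{\kappa^2} values.
#' @export
kappa_squared_series <- function(dipoles) {
  stopifnot(inherits(dipoles, "dipole_series"))
  ct <- rowSums(dipoles$donor_unit * dipoles$acceptor_unit)
  cd <- rowSums(dipoles$donor_unit * dipoles$ree_unit)
  ca <- rowSums(dipoles$acceptor_unit * dipoles$ree_unit)
  (ct - 3 * cd * ca)^2
}

#' Construct a series of unit dipole / end-to-end orientations
#'
#' @param donor_unit,acceptor_unit,ree_unit n x 3 matrices of unit
#'   vectors (donor dipole, acceptor dipole, end-to-end direction).
#' @return An object of class `dipole_series`.
#' @export
dipole_series <- function(donor_unit, acceptor_unit, ree_unit) {
  mats <- list(donor_unit = as.matrix(donor_unit),
               acceptor_unit = as.matrix(acceptor_unit),
               ree_unit = as.matrix(ree_unit))
  n <- nrow(mats[[1L]])
  for (nm in names(mats)) {
    m <- mats[[nm]]
    if (ncol(m) != 3L || nrow(m) != n) stop(nm, ": need matching n x 3")
    if (any(abs(rowSums(m^2) - 1) > 1e-8)) stop(nm, ": vectors not unit norm")
  }
  structure(mats, class = "dipole_series")
}

.unit_rows <- function(m) m / sqrt(rowSums(m^2))

#' Extract all per-frame observables from a trajectory
#'
#' Applies the geometric operations frame by frame and returns aligned
#' traces of \eqn{R_{ee}}, \eqn{R_{C\alpha C\alpha}}, \eqn{R_g} and the
#' unit dipole/end-to-end orientation series.
#'
#' @param frames An [md_frames] object with at least 2 frames.
#' @param labels A [label_map].
#' @return List with elements `ree`, `caca`, `rg` (each a
#'   [distance_trace]) and `dipoles` (a [dipole_series]).
#' @export
extract_traces <- function(frames, labels) {
  stopifnot(inherits(frames, "md_frames"), inherits(labels, "label_map"))
  if (nrow(frames$xyz) < 2L) stop("need at least 2 frames")
  n <- nrow(frames$xyz)
  ree <- caca <- rg <- numeric(n)
  don <- acc <- rv <- matrix(0, n, 3L)
  for (i in seq_len(n)) {
    co <- frame_coords(frames, i)
    ree[i] <- end_to_end_distance(co, labels)
    caca[i] <- ca_ca_distance(co, labels)
    rg[i] <- radius_of_gyration(co, labels)
    don[i, ] <- co[labels$donor_dipole[2L], ] - co[labels$donor_dipole[1L], ]
    acc[i, ] <- co[labels$acceptor_dipole[2L], ] -
      co[labels$acceptor_dipole[1L], ]
    rv[i, ] <- .midpoint(co, labels$diazo_group) -
      .midpoint(co, labels$indole_bond)
  }
  list(ree = distance_trace(frames$times, ree, "Ree"),
       caca = distance_trace(frames$times, caca, "RCaCa"),
       rg = distance_trace(frames$times, rg, "Rg"),
       dipoles = dipole_series(.unit_rows(don), .unit_rows(acc),
                               .unit_rows(rv)))
}
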