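#' Pairwise RMSD after optimal superposition
#'
#' Positional root-mean-square deviation between two conformations over
#' an atom subset, after least-squares superposition (translation +
#' rotation, Kabsch). Superposition removes rigid-body motion, so a
#' rigidly transformed copy has RMSD 0.
#'
#' @param a,b n_atoms x 3 coordinate matrices (nm) of the two
#'   conformations (e.g. from [frame_coords()]).
#' @param atom_subset Integer indices of atoms to superpose and compare
#'   (default all); at least 3.
#' @return RMSD in nm.
#' @export
pairwise_rmsd <- function(a, b, atom_subset = NULL) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  if (is.null(atom_subset)) atom_subset <- seq_len(nrow(a))
  if (length(atom_subset) < 3L) stop("need at least 3 atoms for superposition")
  if (nrow(a) != nrow(b)) stop("atom counts differ")
  av <- as.numeric(t(a[atom_subset, , drop = FALSE]))
  bv <- as.numeric(t(b[atom_subset, , drop = FALSE]))
  inds <- seq_along(av)
  fitted <- bio3d::fit.xyz(av, matrix(bv, nrow = 1L),
                           fixed.inds = inds, mobile.inds = inds)
  sqrt(mean(colSums(matrix((fitted[1L, ] - av)^2, nrow = 3L))))
}

# full pairwise RMSD matrix over an md_frames object (upper triangle
# computed once); used by the clustering driver
.rmsd_matrix <- function(frames, atom_subset) {
  n <- nrow(frames$xyz)
  cols <- as.integer(t(outer(atom_subset, 1:3,
                             function(i, k) 3L * (i - 1L) + k)))
  xyz <- frames$xyz[, cols, drop = FALSE]
  # superpose everything onto frame 1 is NOT sufficient for pairwise
  # RMSD; compute each pair with its own fit
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    ref <- xyz[i, ]
    inds <- seq_along(ref)
    fitted <- bio3d::fit.xyz(ref, xyz[(i + 1L):n, , drop = FALSE],
                             fixed.inds = inds, mobile.inds = inds)
    d2 <- sweep(fitted, 2L, ref)^2
    r <- sqrt(rowSums(d2) / (length(ref) / 3L))
    m[i, (i + 1L):n] <- r
    m[(i + 1L):n, i] <- r
  }
  m
}

#' Daura (GROMOS-style) RMSD conformational clustering
#'
#' Greedy neighbor-count clustering: repeatedly find the structure with
#' the largest number of neighbors within `cutoff` RMSD, make it a
#' cluster center, assign it and its neighbors to that cluster, remove
#' them, and iterate until every structure is assigned. Ties in
#' neighbor count are broken toward the lower structure index, making
#' the result deterministic. Cluster ids are 0-based and ordered by
#' population (id 0 = most populated; population ties keep extraction
#' order).
#'
#' @param frames An [md_frames] object (typically stride-sampled).
#' @param cutoff Neighbor cutoff RMSD (nm), positive.
#' @param atom_subset Atom indices used for RMSD (default: all atoms;
#'   in practice the heavy atoms of a [label_map]).
#' @param stride Keep every `stride`-th frame before clustering
#'   (default 1).
#' @return An object of class `cluster_result`: `assignments` (0-based
#'   cluster id per retained structure, in time order), `centers`
#'   (structure index of each center, 1-based into the retained set),
#'   `populations` (non-increasing), `cutoff`, `n_structures`.
#' @export
daura_cluster <- function(frames, cutoff, atom_subset = NULL, stride = 1L) {
  stopifnot(inherits(frames, "md_frames"))
  if (cutoff <= 0) stop("cutoff must be positive")
  keep <- seq(1L, nrow(frames$xyz), by = as.integer(stride))
  sub <- md_frames(frames$xyz[keep, , drop = FALSE], frames$times[keep])
  n <- nrow(sub$xyz)
  if (is.null(atom_subset)) atom_subset <- seq_len(sub$n_atoms)
  if (n == 1L) {
    return(structure(list(assignments = 0L, centers = 1L,
                          populations = 1L, cutoff = cutoff,
                          n_structures = 1L),
                     class = "cluster_result"))
  }
  dm <- .rmsd_matrix(sub, atom_subset)
  adj <- dm <= cutoff  # includes self (diagonal 0)
  active <- rep(TRUE, n)
  assign_raw <- rep(NA_integer_, n)
  centers <- integer(0)
  pops <- integer(0)
  cl <- 0L
  while (any(active)) {
    counts <- as.integer(adj %*% active)
    counts[!active] <- -1L
    center <- which.max(counts)  # which.max: first max = lowest index
    members <- which(active & adj[center, ])
    assign_raw[members] <- cl
    centers <- c(centers, center)
    pops <- c(pops, length(members))
    active[members] <- FALSE
    cl <- cl + 1L
  }
  # relabel so id 0 is most populated (stable sort keeps extraction
  # order on ties)
  ord <- order(-pops)
  relabel <- integer(length(pops))
  relabel[ord] <- seq_along(pops) - 1L
  structure(list(assignments = relabel[assign_raw + 1L],
                 centers = centers[ord],
                 populations = pops[ord],
                 cutoff = cutoff, n_structures = n),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result: %d structures, %d clusters, cutoff %.3g nm>\n",
              x$n_structures, length(x$populations), x$cutoff))
  cat("populations:", utils::head(x$populations, 10L),
      if (length(x$populations) > 10L) "..." else "", "\n")
  invisible(x)
}

#' Cumulative number of distinct clusters over time
#'
#' Element t is the number of distinct cluster ids seen in
#' `assignments[1..t]`; a plateau indicates converged conformational
#' sampling.
#'
#' @param assignments Integer cluster ids in time order.
#' @return Non-decreasing integer vector, same length.
#' @examples
#' cumulative_cluster_curve(c(0, 0, 1, 0, 2))  # 1 1 2 2 3
#' @export
cumulative_cluster_curve <- function(assignments) {
  if (length(assignments) == 0L) stop("empty assignment vector")
  cumsum(!duplicated(assignments))
}
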