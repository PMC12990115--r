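# Independent oracles used across tests. These deliberately do not call
# the package's own code paths.

# Kabsch superposition RMSD from first principles (SVD of the
# covariance matrix with proper-rotation correction).
kabsch_rmsd <- function(a, b) {
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  h <- t(ac) %*% bc
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  ar <- ac %*% t(rot)
  sqrt(mean(rowSums((ar - bc)^2)))
}

# Direct O(N^2) biased autocorrelation estimator.
naive_acf <- function(x, max_lag) {
  x <- x - mean(x)
  n <- length(x)
  v <- sum(x^2) / n
  vapply(0:max_lag, function(k)
    sum(x[1:(n - k)] * x[(1 + k):n]) / n / v, numeric(1))
}

# Exhaustive reference of the greedy neighbor-count clustering, driven
# by a precomputed distance matrix (itself from kabsch_rmsd).
reference_daura <- function(dm, cutoff) {
  n <- nrow(dm)
  adj <- dm <= cutoff
  active <- rep(TRUE, n)
  assign <- rep(NA_integer_, n)
  pops <- integer(0)
  cl <- 0L
  while (any(active)) {
    counts <- vapply(seq_len(n), function(i)
      if (active[i]) sum(adj[i, ] & active) else -1L, integer(1))
    center <- which.max(counts)
    members <- which(active & adj[center, ])
    assign[members] <- cl
    pops <- c(pops, length(members))
    active[members] <- FALSE
    cl <- cl + 1L
  }
  ord <- order(-pops)
  relabel <- integer(length(pops))
  relabel[ord] <- seq_along(pops) - 1L
  list(assignments = relabel[assign + 1L], populations = sort(pops, TRUE))
}

# A random rigid transform (proper rotation + translation).
rigid_transform <- function(coords, seed = 1) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  rot <- matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
    2 * (q[2] * q[4] + q[1] * q[3]),
    2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
    2 * (q[3] * q[4] - q[1] * q[2]),
    2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
    1 - 2 * (q[2]^2 + q[3]^2)), 3, 3, byrow = TRUE)
  sweep(coords %*% t(rot), 2, rnorm(3), "+")
}

# Random frame set: n_frames of n_atoms each, as md_frames.
random_frames <- function(n_frames, n_atoms, seed = 1, spread = 0.5) {
  set.seed(seed)
  xyz <- matrix(rnorm(n_frames * 3 * n_atoms, sd = spread),
                n_frames, 3 * n_atoms)
  md_frames(xyz, seq_len(n_frames) - 1)
}

# Label map treating all atoms as equal-mass heavies; pairs chosen from
# the first/last atoms.
simple_labels <- function(n_atoms, masses = rep(1, n_atoms)) {
  label_map(indole_bond = c(1, 2), diazo_group = c(n_atoms - 1, n_atoms),
            donor_dipole = c(1, 2), acceptor_dipole = c(n_atoms - 1, n_atoms),
            terminal_ca = c(1, n_atoms), heavy_atoms = seq_len(n_atoms),
            masses = masses)
}
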