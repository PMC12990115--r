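#' Ornstein-Uhlenbeck distance trace with known relaxation time
#'
#' Exact-discretization OU path emulating a stationary end-to-end
#' distance time series:
#' \deqn{x_{t+1} = \mu + (x_t - \mu) e^{-dt/\tau}
#'   + \sigma\sqrt{1 - e^{-2 dt/\tau}}\,\xi_t}
#' started from the stationary distribution. Values are clipped at a
#' small positive floor (1e-3 nm) to respect distance positivity;
#' clipping is rare for the default parameterization and the clip
#' count is reported as an attribute.
#'
#' @param mean Stationary mean (nm), default 0.9.
#' @param relaxation_time Relaxation time \eqn{\tau} (ps), positive.
#' @param stationary_std Stationary standard deviation (nm),
#'   non-negative (0 gives a constant trace).
#' @param n Number of samples.
#' @param dt Sampling interval (ps).
#' @param seed Integer seed; fully determines the output.
#' @return A [distance_trace]; attribute `n_clipped` counts floored
#'   samples.
#' @export
gen_ou_trace <- function(mean = 0.9, relaxation_time = 100,
                         stationary_std = 0.2, n = 10000L, dt = 1,
                         seed = 1L) {
  if (relaxation_time <= 0) stop("relaxation_time must be positive")
  if (stationary_std < 0) stop("stationary_std must be non-negative")
  set.seed(seed)
  a <- exp(-dt / relaxation_time)
  s <- stationary_std * sqrt(1 - a^2)
  x <- numeric(n)
  x[1L] <- mean + stationary_std * stats::rnorm(1L)
  noise <- stats::rnorm(n - 1L)
  for (i in 2:n) x[i] <- mean + (x[i - 1L] - mean) * a + s * noise[i - 1L]
  clipped <- x < 1e-3
  x[clipped] <- 1e-3
  tr <- distance_trace((seq_len(n) - 1L) * dt, x, "ou")
  attr(tr, "n_clipped") <- sum(clipped)
  tr
}

#' Fractional Gaussian noise via circulant embedding
#'
#' Davies-Harte synthesis: the fGn autocovariance
#' \eqn{\gamma(k) = \tfrac12(|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H})} is
#' embedded in a circulant matrix whose eigenvalues (an FFT of the
#' first row) are all non-negative for fGn, giving an exact unit-
#' variance stationary sample.
#'
#' @param H Hurst parameter in (0, 1).
#' @param n Output length; a power of two.
#' @param seed Integer seed.
#' @return Numeric vector of length `n`, unit variance in expectation.
#' @export
gen_fgn <- function(H, n, seed = 1L) {
  if (H <= 0 || H >= 1) stop("H must lie in (0, 1)")
  n <- as.integer(n)
  if (bitwAnd(n, n - 1L) != 0L) stop("n must be a power of two")
  set.seed(seed)
  m <- 2L * n
  k <- 0:n
  g <- 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  row1 <- c(g, rev(g[2:n]))
  lam <- Re(stats::fft(row1))
  lam[lam < 0] <- 0  # guard tiny negative round-off
  z <- complex(real = stats::rnorm(m), imaginary = stats::rnorm(m))
  Re(stats::fft(sqrt(lam / (2 * m)) * z))[seq_len(n)] * sqrt(2)
}

#' Power-law (1/f^alpha) noise by spectral synthesis
#'
#' Builds a spectrum with amplitudes \eqn{|f|^{-\alpha/2}} and
#' uniformly random phases, inverse-transforms, and rescales to unit
#' standard deviation. \eqn{\alpha = 0} gives white noise,
#' \eqn{\alpha = 1} pink (1/f) noise, \eqn{\alpha = 2} Brownian-like
#' noise.
#'
#' @param alpha Spectral exponent in [0, 2.5].
#' @param n Output length (even).
#' @param seed Integer seed.
#' @return Numeric vector of length `n`, unit standard deviation.
#' @export
gen_powerlaw_noise <- function(alpha, n, seed = 1L) {
  if (alpha < 0 || alpha > 2.5) stop("alpha must lie in [0, 2.5]")
  n <- as.integer(n)
  if (n %% 2L != 0L) stop("n must be even")
  set.seed(seed)
  nf <- n %/% 2L
  f <- (1:nf) / n
  amp <- f^(-alpha / 2)
  ph <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = ph)
  full <- c(0, spec, Conj(rev(spec[-nf])))
  x <- Re(stats::fft(full, inverse = TRUE))
  x / stats::sd(x)
}

#' Sample end-to-end distances from the skewed-Gaussian mixture
#'
#' Rejection sampling from the Jacobian-weighted mixture density
#' [skewed_gaussian_density()]. Component amplitudes are derived from
#' the requested mixture weights by numerically normalizing each
#' component, so `weights` are the actual component probabilities.
#'
#' @param centers,widths Component centers \eqn{r_j^0} and widths
#'   \eqn{\sigma_j} (nm).
#' @param weights Component probabilities (normalized internally).
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return Positive numeric vector of length `n`; attribute
#'   `amplitudes` carries the density amplitudes \eqn{A_j} used.
#' @export
gen_mixture_samples <- function(centers = c(0.45, 0.90, 1.30),
                                widths = c(0.08, 0.12, 0.15),
                                weights = c(0.3, 0.5, 0.2),
                                n = 50000L, seed = 1L) {
  stopifnot(length(centers) == length(widths),
            length(widths) == length(weights))
  if (any(widths <= 0) || any(weights <= 0)) stop("invalid parameters")
  weights <- weights / sum(weights)
  set.seed(seed)
  upper <- max(centers + 6 * widths)
  I <- vapply(seq_along(centers), function(j)
    stats::integrate(function(R) R^2 *
                       exp(-0.5 * ((R - centers[j]) / widths[j])^2),
                     0, upper)$value, numeric(1L))
  A <- weights / I
  grid <- seq(1e-4, upper, length.out = 4096L)
  fmax <- max(skewed_gaussian_density(grid, A, centers, widths)) * 1.05
  out <- numeric(0)
  while (length(out) < n) {
    m <- 2L * (n - length(out)) + 1000L
    x <- stats::runif(m, 0, upper)
    u <- stats::runif(m, 0, fmax)
    out <- c(out, x[u < skewed_gaussian_density(x, A, centers, widths)])
  }
  out <- out[seq_len(n)]
  attr(out, "amplitudes") <- A
  out
}

#' Isotropically distributed dipole/end-to-end orientations
#'
#' Donor, acceptor and end-to-end unit vectors drawn i.i.d. uniformly
#' on the sphere; the Monte-Carlo oracle for the isotropic
#' \eqn{\langle\kappa^2\rangle = 2/3} limit.
#'
#' @param n Number of orientation triples.
#' @param seed Integer seed.
#' @return A [dipole_series].
#' @export
gen_random_dipoles <- function(n, seed = 1L) {
  set.seed(seed)
  rand_units <- function(n) {
    m <- matrix(stats::rnorm(3L * n), n, 3L)
    m / sqrt(rowSums(m^2))
  }
  dipole_series(rand_units(n), rand_units(n), rand_units(n))
}

#' Toy bead-chain trajectory with tunable stiffness
#'
#' Overdamped Euler-Maruyama dynamics of a harmonic-bond chain with an
#' angular stiffness term, intended as a schematic stand-in for a
#' labeled peptide: low bending stiffness gives a flexible, compact
#' (GS-like) chain, high stiffness an extended (polyproline-like) one.
#' No excluded volume; the chain exists to exercise the geometry,
#' clustering and landscape code paths, not to model peptides
#' quantitatively.
#'
#' @param n_beads Number of beads (>= 4).
#' @param bond_length Equilibrium bond length (nm).
#' @param bending_stiffness Angular stiffness in kT units (0 =
#'   freely jointed).
#' @param n_frames Number of output frames.
#' @param dt Output frame spacing (ps).
#' @param seed Integer seed.
#' @param n_steps_per_frame Integration substeps between frames.
#' @return List with `frames` (an [md_frames]) and `labels` (a
#'   [label_map] using the first/last bonds as fluorophore proxies and
#'   terminal beads as C-alphas).
#' @export
gen_bead_chain <- function(n_beads = 8L, bond_length = 0.38,
                           bending_stiffness = 2, n_frames = 100L,
                           dt = 2, seed = 1L, n_steps_per_frame = 20L) {
  n_beads <- as.integer(n_beads)
  if (n_beads < 4L) stop("need at least 4 beads")
  set.seed(seed)
  kb <- 800     # bond stiffness, kT/nm^2
  ka <- bending_stiffness
  h <- 0.0002   # integration step (arbitrary friction units)
  pos <- cbind((seq_len(n_beads) - 1L) * bond_length, 0, 0) +
    matrix(stats::rnorm(3L * n_beads, 0, 0.01), n_beads, 3L)
  forces <- function(p) {
    f <- matrix(0, n_beads, 3L)
    dv <- p[-1L, , drop = FALSE] - p[-n_beads, , drop = FALSE]
    dl <- sqrt(rowSums(dv^2))
    fb <- kb * (dl - bond_length) / dl
    fvec <- dv * fb
    f[-n_beads, ] <- f[-n_beads, ] + fvec
    f[-1L, ] <- f[-1L, ] - fvec
    if (ka > 0 && n_beads >= 3L) {
      # bending: penalize deviation of consecutive unit bonds
      u <- dv / dl
      for (i in 2:(n_beads - 1L)) {
        # force from potential ka * (1 - u[i-1].u[i])
        a <- u[i - 1L, ]; b <- u[i, ]
        dot <- sum(a * b)
        ga <- ka * (b - dot * a) / dl[i - 1L]
        gb <- ka * (a - dot * b) / dl[i]
        f[i - 1L, ] <- f[i - 1L, ] - ga
        f[i, ] <- f[i, ] + ga - gb
        f[i + 1L, ] <- f[i + 1L, ] + gb
      }
    }
    f
  }
  xyz <- matrix(0, n_frames, 3L * n_beads)
  sq <- sqrt(2 * h)
  for (fr in seq_len(n_frames)) {
    for (s in seq_len(n_steps_per_frame)) {
      pos <- pos + h * forces(pos) +
        sq * matrix(stats::rnorm(3L * n_beads), n_beads, 3L)
    }
    xyz[fr, ] <- as.numeric(t(pos))
  }
  frames <- md_frames(xyz, (seq_len(n_frames) - 1L) * dt)
  labels <- label_map(indole_bond = c(1L, 2L),
                      diazo_group = c(n_beads - 1L, n_beads),
                      donor_dipole = c(1L, 2L),
                      acceptor_dipole = c(n_beads - 1L, n_beads),
                      terminal_ca = c(1L, n_beads),
                      heavy_atoms = seq_len(n_beads),
                      masses = rep(100, n_beads))
  list(frames = frames, labels = labels)
}

#' Synthetic cosine velocity profile with known viscosity
#'
#' Generates \eqn{v_z(x) = [\rho A / (\eta k^2)] \cos(kx)} plus
#' Gaussian noise, inverting the same closed form the analysis uses,
#' so the noiseless round trip is exact.
#'
#' @param eta_true Target shear viscosity (mPa s).
#' @param perturbation A [periodic_perturbation].
#' @param rho Density (kg/m^3), default 972 (typical SPC water).
#' @param noise_std Gaussian noise on the velocities (nm/ps).
#' @param n_points Number of profile points.
#' @param seed Integer seed.
#' @return List with `x` (nm), `vz` (nm/ps) and attribute-style
#'   elements `V_true` (nm/ps) and `eta_true`.
#' @export
gen_velocity_profile <- function(eta_true = 0.445,
                                 perturbation = periodic_perturbation(),
                                 rho = 972, noise_std = 0,
                                 n_points = 64L, seed = 1L) {
  if (eta_true <= 0) stop("eta_true must be positive")
  set.seed(seed)
  inv_eta <- 1 / (eta_true * 1e-3)  # m s kg^-1
  # invert: 1/eta = V k^2 / (rho A) * 1e6  ->  V in nm/ps
  V <- inv_eta * rho * perturbation$amplitude /
    (perturbation$k^2 * 1e6)
  x <- (seq_len(n_points) - 0.5) / n_points * perturbation$box_length
  vz <- V * cos(perturbation$k * x)
  if (noise_std > 0) vz <- vz + stats::rnorm(n_points, 0, noise_std)
  list(x = x, vz = vz, V_true = V, eta_true = eta_true)
}
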