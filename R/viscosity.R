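#' Periodic cosine acceleration perturbation
#'
#' The nonequilibrium perturbation \eqn{a_z(x) = A \cos(2\pi x / L_x)}
#' applied along z; the steady-state velocity-profile amplitude it
#' induces carries the shear viscosity.
#'
#' @param amplitude Acceleration amplitude A (nm ps^-2); the reference
#'   protocol uses 0.025.
#' @param box_length Box edge \eqn{L_x} (nm).
#' @return Object of class `periodic_perturbation` with `amplitude`,
#'   `box_length`, `k` (wavenumber \eqn{2\pi/L_x}, nm^-1).
#' @export
periodic_perturbation <- function(amplitude = 0.025, box_length = 5.0) {
  if (box_length <= 0) stop("box_length must be positive")
  structure(list(amplitude = amplitude, box_length = box_length,
                 k = 2 * pi / box_length),
            class = "periodic_perturbation")
}

#' Least-squares amplitude of a cosine velocity profile
#'
#' Projects the measured \eqn{v_z(x)} onto \eqn{\cos(kx)} (ordinary
#' least squares with the single cosine basis function), returning the
#' profile amplitude V.
#'
#' @param x_positions Positions across the box (nm).
#' @param vz_values Velocities \eqn{v_z} at those positions (nm/ps).
#' @param perturbation A [periodic_perturbation].
#' @return Amplitude V in nm/ps (0 for an all-zero profile).
#' @export
fit_profile_amplitude <- function(x_positions, vz_values, perturbation) {
  stopifnot(inherits(perturbation, "periodic_perturbation"))
  if (length(x_positions) != length(vz_values)) stop("mismatched lengths")
  if (length(x_positions) < 8L) stop("need at least 8 profile points")
  basis <- cos(perturbation$k * x_positions)
  sum(basis * vz_values) / sum(basis^2)
}

#' Instantaneous inverse viscosity from a profile amplitude
#'
#' For the cosine forcing, steady-state Navier-Stokes gives the
#' profile amplitude \eqn{V = \rho A / (\eta k^2)}, hence
#' \deqn{1/\eta = V k^2 / (\rho A)}
#' Inputs in MD units (nm, ps) are converted so the result is in SI
#' m s kg^-1 (the reciprocal of Pa s).
#'
#' @param V Velocity-profile amplitude (nm/ps).
#' @param perturbation A [periodic_perturbation].
#' @param rho Fluid mass density (kg/m^3).
#' @return Inverse viscosity in m s kg^-1. V = 0 returns 0 (infinite
#'   viscosity; degenerate profile).
#' @export
instantaneous_inverse_viscosity <- function(V, perturbation, rho) {
  stopifnot(inherits(perturbation, "periodic_perturbation"))
  if (perturbation$amplitude == 0) stop("zero perturbation amplitude")
  if (rho <= 0) stop("density must be positive")
  # V k^2 / A in MD units: (nm/ps)(nm^-2)/(nm ps^-2) = ps nm^-2
  # 1 ps nm^-2 = 1e-12 s / 1e-18 m^2 = 1e6 s m^-2
  (V * perturbation$k^2 / perturbation$amplitude) * 1e6 / rho
}

#' Summarize an inverse-viscosity time series
#'
#' The shear viscosity is the reciprocal of the mean inverse
#' viscosity, \eqn{\eta = 1 / \overline{(1/\eta)}}; the statistical
#' error comes from block averaging of the inverse-viscosity series,
#' propagated through the reciprocal.
#'
#' @param inv_eta_series Inverse-viscosity samples (m s kg^-1),
#'   length >= 4, positive mean.
#' @return Object of class `viscosity_estimate`: `eta` (mPa s),
#'   `inv_eta_mean` (m s kg^-1), `error` (mPa s), `block` (the
#'   underlying [block_average_error()] result).
#' @examples
#' summarize_viscosity(rep(2245.61, 10))  # eta = 0.445 mPa s
#' @export
summarize_viscosity <- function(inv_eta_series) {
  ba <- block_average_error(inv_eta_series)
  if (ba$mean <= 0) stop("non-positive mean inverse viscosity")
  eta_pas <- 1 / ba$mean                  # Pa s
  err_pas <- ba$error / ba$mean^2         # |d(1/x)| = dx / x^2
  structure(list(eta = eta_pas * 1e3, inv_eta_mean = ba$mean,
                 error = err_pas * 1e3, block = ba),
            class = "viscosity_estimate")
}

#' @export
print.viscosity_estimate <- function(x, ...) {
  cat(sprintf("<viscosity_estimate: eta = %.4g +/- %.2g mPa s (1/eta = %.6g m s/kg)>\n",
              x$eta, x$error, x$inv_eta_mean))
  invisible(x)
}

#' Viscosity from a series of velocity-profile snapshots
#'
#' Fits each profile's cosine amplitude, converts to instantaneous
#' inverse viscosities, and summarizes with block-averaged errors.
#'
#' @param profiles List of profiles, each a list/data.frame with
#'   elements `x` (nm) and `vz` (nm/ps).
#' @param perturbation A [periodic_perturbation].
#' @param rho Fluid density (kg/m^3).
#' @return A `viscosity_estimate` (see [summarize_viscosity()]).
#' @export
viscosity_from_profiles <- function(profiles, perturbation, rho) {
  inv <- vapply(profiles, function(p) {
    V <- fit_profile_amplitude(p$x, p$vz, perturbation)
    instantaneous_inverse_viscosity(V, perturbation, rho)
  }, numeric(1L))
  summarize_viscosity(inv)
}
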