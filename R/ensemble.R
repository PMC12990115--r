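#' Skewed-Gaussian mixture density for end-to-end distances
#'
#' Density (up to the fitted amplitudes) of the distance-distribution
#' model: a sum of Jacobian-weighted Gaussian terms
#' \deqn{P(R) = \sum_j A_j R^2 \exp[-\tfrac12 ((R - r_j^0)/\sigma_j)^2]}
#' The \eqn{R^2} factor is the polymer end-to-end Jacobian, which skews
#' each Gaussian toward larger distances.
#'
#' @param r Distances (nm) at which to evaluate.
#' @param amplitude,center,width Vectors of per-component parameters
#'   \eqn{A_j}, \eqn{r_j^0} (nm), \eqn{\sigma_j} (nm).
#' @return Density values (same length as `r`).
#' @export
skewed_gaussian_density <- function(r, amplitude, center, width) {
  stopifnot(length(amplitude) == length(center),
            length(center) == length(width))
  out <- numeric(length(r))
  for (j in seq_along(amplitude))
    out <- out + amplitude[j] * r^2 *
      exp(-0.5 * ((r - center[j]) / width[j])^2)
  out
}

# histogram of samples with Freedman-Diaconis bin width, density scale
.fd_hist <- function(samples) {
  bw <- 2 * stats::IQR(samples) / length(samples)^(1 / 3)
  if (bw <= 0) bw <- diff(range(samples)) / 50
  brk <- seq(min(samples), max(samples) + bw, by = bw)
  graphics::hist(samples, breaks = brk, plot = FALSE)
}

#' Fit the skewed-Gaussian mixture to an end-to-end distance sample
#'
#' Histograms the sample (Freedman-Diaconis bin width, density
#' normalization) and fits the [skewed_gaussian_density()] model by
#' bounded nonlinear least squares with multi-start initialization
#' seeded from histogram peaks.
#'
#' @param samples Positive distances (nm), at least 100.
#' @param n_components Number of mixture components (default 3).
#' @param n_starts Number of multi-start initializations (default 10).
#' @return An object of class `mixture_fit`: list with `components`
#'   (data.frame `amplitude`, `center`, `width`, sorted by center
#'   ascending, ties by width), `residual` (sum of squared deviations
#'   from the histogram density), `n_samples`, and `histogram`.
#' @export
fit_ree_distribution <- function(samples, n_components = 3L, n_starts = 10L) {
  samples <- as.numeric(samples)
  if (length(samples) < 100L) stop("need at least 100 samples")
  if (any(samples <= 0)) stop("distances must be positive")
  if (stats::sd(samples) == 0) stop("zero variance in samples")
  k <- as.integer(n_components)
  h <- .fd_hist(samples)
  xh <- h$mids
  yh <- h$density

  # candidate centers: local maxima of the histogram, tallest first
  dy <- diff(yh)
  peaks <- which(c(FALSE, dy[-length(dy)] > 0 & dy[-1L] <= 0, FALSE))
  if (length(peaks) == 0L) peaks <- which.max(yh)
  peaks <- peaks[order(yh[peaks], decreasing = TRUE)]
  rng <- diff(range(samples))
  s0 <- stats::sd(samples) / max(1, k)

  model_fn <- function(par) {
    skewed_gaussian_density(xh, par[seq_len(k)],
                            par[k + seq_len(k)], par[2 * k + seq_len(k)])
  }
  lower <- c(rep(1e-10, k), rep(1e-4, k), rep(1e-3, k))
  upper <- c(rep(1e3, k), rep(max(samples), k), rep(rng, k))

  starts <- vector("list", n_starts)
  base_centers <- xh[peaks]
  for (s in seq_len(n_starts)) {
    ctr <- if (length(base_centers) >= k && s == 1L) {
      sort(base_centers[seq_len(k)])
    } else {
      # spread quantile-based starts, jittered deterministically per start
      stats::quantile(samples, probs = (seq_len(k) - 0.5) / k) *
        (1 + 0.05 * sin(s * seq_len(k)))
    }
    starts[[s]] <- c(rep(max(yh) / max(1e-12, max(xh)^2), k),
                     pmin(pmax(as.numeric(ctr), lower[k + 1]), upper[k + 1]),
                     rep(s0 * (0.5 + s / n_starts), k))
  }

  best <- NULL
  best_rss <- Inf
  for (st in starts) {
    names(st) <- paste0("p", seq_along(st))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st,
                         fn = function(p) yh - model_fn(p),
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.finite(rss) && rss < best_rss) {
      best_rss <- rss
      best <- fit
    }
  }
  if (is.null(best)) stop("mixture fit failed to converge from any start")
  p <- unname(best$par)
  comp <- data.frame(amplitude = p[seq_len(k)],
                     center = p[k + seq_len(k)],
                     width = p[2 * k + seq_len(k)])
  comp <- comp[order(comp$center, comp$width), , drop = FALSE]
  rownames(comp) <- NULL
  structure(list(components = comp, residual = best_rss,
                 n_samples = length(samples),
                 histogram = list(mids = xh, density = yh)),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit: %d components, n = %d, residual = %.4g>\n",
              nrow(x$components), x$n_samples, x$residual))
  print(round(x$components, 4))
  invisible(x)
}

#' Boltzmann-inversion free-energy landscape over (Rg, SASA)
#'
#' Bins the joint samples on a `bins x bins` grid spanning the data
#' ranges and converts occupancies to free energies,
#' \deqn{\Delta F = -RT \ln(n / N)} in kJ/mol. Empty cells are `NA`
#' (masked), so the surface carries no infinite sentinels.
#'
#' @param rg Radius-of-gyration samples (nm).
#' @param sasa Solvent-accessible surface-area samples (nm^2), same
#'   length (SASA is consumed as a precomputed input, never computed
#'   here).
#' @param temperature Temperature in K (default 300).
#' @param bins Grid size per axis (default 50).
#' @return An object of class `free_energy_grid`: list with `rg_edges`,
#'   `sasa_edges` (length `bins + 1`), `delta_f` (`bins x bins` matrix,
#'   kJ/mol, `NA` where empty), `counts`, `temperature`, `n_total`.
#' @export
free_energy_surface <- function(rg, sasa, temperature = 300, bins = 50L) {
  if (length(rg) != length(sasa)) stop("mismatched lengths")
  if (length(rg) < 1L) stop("need at least one sample")
  if (temperature <= 0) stop("temperature must be positive")
  bins <- as.integer(bins)
  span <- function(x) {
    r <- range(x)
    if (r[1L] == r[2L]) r <- r + c(-0.5, 0.5)  # degenerate axis
    seq(r[1L], r[2L], length.out = bins + 1L)
  }
  re <- span(rg)
  se <- span(sasa)
  ix <- findInterval(rg, re, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(sasa, se, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(0L, bins, bins)
  tb <- table(factor(ix, levels = seq_len(bins)),
              factor(iy, levels = seq_len(bins)))
  counts[] <- as.integer(tb)
  N <- length(rg)
  df <- -.R_GAS_KJ * temperature * log(counts / N)
  df[counts == 0L] <- NA_real_
  structure(list(rg_edges = re, sasa_edges = se, delta_f = df,
                 counts = counts, temperature = temperature, n_total = N),
            class = "free_energy_grid")
}

#' @export
print.free_energy_grid <- function(x, ...) {
  occ <- sum(!is.na(x$delta_f))
  cat(sprintf(
    "<free_energy_grid: %dx%d, %d occupied cells, N = %d, T = %g K>\n",
    nrow(x$delta_f), ncol(x$delta_f), occ, x$n_total, x$temperature))
  invisible(x)
}

#' Block-averaging standard error of a correlated series
#'
#' Splits the series into contiguous blocks of geometrically spaced
#' sizes; for each block size the error estimate is the standard
#' deviation of block means divided by the square root of the number of
#' blocks. For correlated data the estimate grows with block size until
#' blocks are longer than the correlation time, then plateaus; the
#' reported error is taken at the largest block size with at least 4
#' blocks.
#'
#' @param series Numeric vector, length at least 4.
#' @param n_block_sizes Number of block sizes to scan (default 20).
#' @return An object of class `block_average`: list with `mean`,
#'   `error`, `block_sizes`, `block_errors`.
#' @export
block_average_error <- function(series, n_block_sizes = 20L) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 4L) stop("series shorter than 4")
  max_b <- n %/% 4L
  sizes <- unique(round(exp(seq(0, log(max_b), length.out = n_block_sizes))))
  errs <- vapply(sizes, function(b) {
    nb <- n %/% b
    bm <- colMeans(matrix(series[seq_len(nb * b)], nrow = b))
    stats::sd(bm) / sqrt(nb)
  }, numeric(1L))
  err <- errs[length(errs)]
  if (!is.finite(err)) err <- 0
  structure(list(mean = mean(series), error = err,
                 block_sizes = sizes, block_errors = errs),
            class = "block_average")
}

#' @export
print.block_average <- function(x, ...) {
  cat(sprintf("<block_average: mean = %.6g +/- %.3g (%d block sizes)>\n",
              x$mean, x$error, length(x$block_sizes)))
  invisible(x)
}
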