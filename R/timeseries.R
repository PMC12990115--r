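#' Normalized autocorrelation function via FFT
#'
#' Mean-subtracted, variance-normalized ACF computed with a
#' zero-padded FFT (no circular wrap-around), using the biased
#' normalization (divide by N) so the estimate is positive
#' semidefinite. Also locates the first zero crossing \eqn{\tau_0} and
#' the integrated correlation time up to it.
#'
#' @param trace A [distance_trace], or a plain numeric vector (then
#'   `dt` supplies the sampling interval).
#' @param dt Sampling interval in ps when `trace` is a bare vector.
#' @param max_lag Largest lag to keep (samples); default `N - 1`.
#' @return An object of class `acf_result`: `lags` (ps), `C`
#'   (with `C[1] = 1` at lag 0), `tau0` (ps, first zero crossing,
#'   linearly interpolated; `NA` if none), `tau_corr` (ps, see
#'   [integrated_correlation_time()]), `no_crossing` (logical flag).
#' @export
autocorrelation <- function(trace, dt = 1, max_lag = NULL) {
  if (inherits(trace, "distance_trace")) {
    x <- trace$values
    dt <- trace$dt
  } else x <- as.numeric(trace)
  n <- length(x)
  if (n < 16L) stop("trace too short for ACF (need >= 16 samples)")
  x <- x - mean(x)
  if (sum(x^2) == 0) stop("zero-variance trace")
  m <- 2L^ceiling(log2(2L * n))
  sp <- abs(stats::fft(c(x, rep(0, m - n))))^2
  ac <- Re(stats::fft(sp, inverse = TRUE))[seq_len(n)] / m
  C <- (ac / n) / (ac[1L] / n)  # biased estimator, normalized
  if (is.null(max_lag)) max_lag <- n - 1L
  keep <- seq_len(min(max_lag + 1L, n))
  C <- C[keep]
  lags <- (keep - 1L) * dt
  res <- structure(list(lags = lags, C = C, tau0 = NA_real_,
                        tau_corr = NA_real_, no_crossing = FALSE),
                   class = "acf_result")
  ic <- integrated_correlation_time(res, recompute = TRUE)
  res$tau0 <- attr(ic, "tau0")
  res$no_crossing <- attr(ic, "no_crossing")
  res$tau_corr <- as.numeric(ic)
  res
}

#' @export
print.acf_result <- function(x, ...) {
  cat(sprintf("<acf_result: %d lags, tau0 = %.4g ps, tau_corr = %.4g ps%s>\n",
              length(x$lags), x$tau0, x$tau_corr,
              if (x$no_crossing) " [no zero crossing]" else ""))
  invisible(x)
}

#' Integrated correlation time of an ACF
#'
#' Trapezoidal integral of the normalized ACF from lag 0 to its first
#' zero crossing \eqn{\tau_0} (the crossing point is located by linear
#' interpolation between the bracketing lags). If the ACF never
#' crosses zero within the available lags, the integral runs to the
#' maximum lag and the result is flagged.
#'
#' @param acf An `acf_result` from [autocorrelation()].
#' @param recompute Internal flag; users can ignore it.
#' @return Correlation time in ps. Attributes `tau0` and `no_crossing`
#'   carry the crossing point and the flag.
#' @export
integrated_correlation_time <- function(acf, recompute = FALSE) {
  stopifnot(inherits(acf, "acf_result"))
  if (!recompute && !is.na(acf$tau_corr)) {
    out <- acf$tau_corr
    attr(out, "tau0") <- acf$tau0
    attr(out, "no_crossing") <- acf$no_crossing
    return(out)
  }
  C <- acf$C
  lags <- acf$lags
  neg <- which(C < 0)
  if (length(neg) == 0L) {
    tau0 <- lags[length(lags)]
    no_cross <- TRUE
    kend <- length(C)
    tint <- 0
  } else {
    k <- neg[1L]  # first negative lag; crossing between k-1 and k
    frac <- C[k - 1L] / (C[k - 1L] - C[k])
    tau0 <- lags[k - 1L] + frac * (lags[k] - lags[k - 1L])
    no_cross <- FALSE
    kend <- k - 1L
    # triangle between last positive sample and the interpolated zero
    tint <- 0.5 * C[kend] * (tau0 - lags[kend])
  }
  if (kend >= 2L) {
    tint <- tint + sum((C[1:(kend - 1L)] + C[2:kend]) / 2 *
                       diff(lags[1:kend]))
  }
  out <- tint
  attr(out, "tau0") <- tau0
  attr(out, "no_crossing") <- no_cross
  out
}

# Anis-Lloyd expected R/S of an iid series for window size n
.expected_rs <- function(n) {
  i <- seq_len(n - 1L)
  pre <- if (n <= 340) {
    exp(lgamma((n - 1) / 2) - lgamma(n / 2)) / sqrt(pi)
  } else 1 / sqrt(n * pi / 2)
  pre * sum(sqrt((n - i) / i)) * (n - 0.5) / n
}

#' Hurst exponent by rescaled-range (R/S) analysis
#'
#' Classical R/S estimation: for logarithmically spaced window sizes
#' the series is split into disjoint windows; in each window the range
#' of cumulative deviations R is divided by the window standard
#' deviation S, and H is the slope of log(mean R/S) versus log(window
#' size). The default estimate applies the Anis-Lloyd finite-sample
#' correction (the expected R/S of an uncorrelated series deviates
#' from the asymptotic square-root law at small windows, biasing the
#' raw slope upward); the uncorrected slope is also returned.
#'
#' H = 0.5 is memoryless diffusion, H > 0.5 persistent, H < 0.5
#' antipersistent dynamics.
#'
#' @param series Numeric vector (or [distance_trace]), length >= 512,
#'   non-constant.
#' @param min_window Smallest window size (default 16).
#' @param n_sizes Number of window sizes (default 12, spaced up to
#'   N/4).
#' @param corrected Apply the Anis-Lloyd correction (default `TRUE`).
#' @return An object of class `hurst_result`: `H`, `H_raw`,
#'   `window_sizes`, `rs_values`, `fit_r2`.
#' @export
hurst_rs <- function(series, min_window = 16L, n_sizes = 12L,
                     corrected = TRUE) {
  if (inherits(series, "distance_trace")) series <- series$values
  x <- as.numeric(series)
  N <- length(x)
  if (N < 512L) stop("series too short for R/S analysis (need >= 512)")
  if (stats::sd(x) == 0) stop("constant series")
  sizes <- unique(round(exp(seq(log(min_window), log(N %/% 4L),
                                length.out = n_sizes))))
  if (length(sizes) < 5L) stop("fewer than 5 usable window sizes")
  rs <- vapply(sizes, function(n) {
    nb <- N %/% n
    vals <- vapply(seq_len(nb), function(b) {
      w <- x[((b - 1L) * n + 1L):(b * n)]
      s <- stats::sd(w)
      if (s == 0) return(NA_real_)
      y <- cumsum(w - mean(w))
      (max(y) - min(y)) / s
    }, numeric(1L))
    mean(vals, na.rm = TRUE)
  }, numeric(1L))
  ok <- is.finite(rs) & rs > 0
  fit_raw <- stats::lm(log(rs[ok]) ~ log(sizes[ok]))
  h_raw <- unname(stats::coef(fit_raw)[2L])
  if (corrected) {
    ers <- vapply(sizes[ok], .expected_rs, numeric(1L))
    fit <- stats::lm(log(rs[ok] / ers) ~ log(sizes[ok]))
    h <- 0.5 + unname(stats::coef(fit)[2L])
    r2 <- summary(fit_raw)$r.squared
  } else {
    h <- h_raw
    r2 <- summary(fit_raw)$r.squared
  }
  structure(list(H = h, H_raw = h_raw, window_sizes = sizes[ok],
                 rs_values = rs[ok], fit_r2 = r2),
            class = "hurst_result")
}

#' @export
print.hurst_result <- function(x, ...) {
  cat(sprintf("<hurst_result: H = %.3f (raw %.3f), %d window sizes, R2 = %.3f>\n",
              x$H, x$H_raw, length(x$window_sizes), x$fit_r2))
  invisible(x)
}

#' Welch power spectral density with power-law exponent
#'
#' Welch's averaged-periodogram PSD (Hann windows, 50% overlap,
#' per-segment mean removal), followed by a power-law fit
#' \eqn{S(f) \propto f^{-\alpha}} over the high-frequency region: the
#' upper `fit_fraction` of the log-frequency span, capped below
#' `fmax_fraction` of the Nyquist frequency (the discrete-time
#' spectrum flattens near Nyquist, which would bias the slope). The
#' exponent classifies the noise regime: white (fast uncorrelated
#' motions, \eqn{\alpha \approx 0}), 1/f (scale-free dynamics,
#' \eqn{\alpha \approx 1}), Brownian (slow diffusive rearrangements,
#' \eqn{\alpha \approx 2}); thresholds at 0.5 and 1.5.
#'
#' @param series Numeric vector or [distance_trace].
#' @param segment_length Welch segment length (samples); the series
#'   must be at least 4 segments long.
#' @param dt Sampling interval (ps) when `series` is a bare vector.
#' @param fit_fraction Fraction of the log-frequency span (from the
#'   top) used in the power-law fit (default 0.5).
#' @param fmax_fraction Upper frequency cap for the fit as a fraction
#'   of Nyquist (default 0.5).
#' @return An object of class `psd_result`: `freqs` (1/ps), `power`,
#'   `alpha`, `noise_class` (`"white"`, `"one_over_f"` or
#'   `"brownian"`), `fit_range` (Hz-like 1/ps interval).
#' @export
welch_psd <- function(series, segment_length = 1024L, dt = 1,
                      fit_fraction = 0.5, fmax_fraction = 0.5) {
  if (inherits(series, "distance_trace")) {
    dt <- series$dt
    series <- series$values
  }
  x <- as.numeric(series)
  L <- as.integer(segment_length)
  if (length(x) < 4L * L)
    stop("series too short: need at least 4 Welch segments")
  step <- L %/% 2L
  nseg <- (length(x) - L) %/% step + 1L
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1L)) / (L - 1L))  # Hann
  U <- sum(w^2)
  nf <- L %/% 2L
  P <- rep(0, nf + 1L)
  for (s in seq_len(nseg)) {
    seg <- x[((s - 1L) * step + 1L):((s - 1L) * step + L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg))^2 * dt / U
    P <- P + sp[seq_len(nf + 1L)]
  }
  P <- P / nseg
  f <- (0:nf) / (L * dt)
  fny <- f[nf + 1L]
  keep <- f > 0 & f <= fmax_fraction * fny
  lf <- log10(f[keep])
  lp <- log10(pmax(P[keep], .Machine$double.xmin))
  lo <- max(lf) - fit_fraction * (max(lf) - min(lf))
  sel <- lf >= lo
  alpha <- -unname(stats::coef(stats::lm(lp[sel] ~ lf[sel]))[2L])
  cls <- if (alpha < 0.5) "white" else if (alpha < 1.5) "one_over_f" else
    "brownian"
  structure(list(freqs = f, power = P, alpha = alpha, noise_class = cls,
                 fit_range = c(10^lo, fmax_fraction * fny)),
            class = "psd_result")
}

#' @export
print.psd_result <- function(x, ...) {
  cat(sprintf("<psd_result: alpha = %.3f (%s), fit over [%.3g, %.3g] 1/ps>\n",
              x$alpha, x$noise_class, x$fit_range[1L], x$fit_range[2L]))
  invisible(x)
}

#' Classify a spectral exponent into a noise regime
#'
#' @param alpha Spectral exponent.
#' @return `"white"` (alpha < 0.5), `"one_over_f"` (0.5 <= alpha <
#'   1.5) or `"brownian"` (alpha >= 1.5).
#' @export
classify_noise <- function(alpha) {
  if (alpha < 0.5) "white" else if (alpha < 1.5) "one_over_f" else "brownian"
}

#' Zero-lag cross-correlation between two observables
#'
#' Pearson correlation at lag 0, e.g. between \eqn{R_{ee}} and
#' \eqn{R_{C\alpha C\alpha}} to quantify how chain extension couples
#' to terminal backbone separation.
#'
#' @param x,y Numeric vectors or [distance_trace]s of equal length,
#'   both non-constant.
#' @return Correlation coefficient in \eqn{[-1, 1]}.
#' @export
zero_lag_crosscorr <- function(x, y) {
  if (inherits(x, "distance_trace")) x <- x$values
  if (inherits(y, "distance_trace")) y <- y$values
  if (length(x) != length(y)) stop("series lengths differ")
  if (length(x) < 2L) stop("need at least 2 samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  stats::cor(x, y)
}

#' All Table-style dynamical indicators for one observable
#'
#' Bundles [autocorrelation()], [hurst_rs()] and [welch_psd()] into
#' the indicator set reported per observable: integrated correlation
#' time, Hurst exponent, spectral exponent and noise class.
#'
#' @param trace A [distance_trace].
#' @param segment_length Welch segment length; defaults to
#'   `min(1024, N/4)` rounded down to a power of two.
#' @return List with `tau_corr` (ps), `tau0` (ps), `H`, `alpha`,
#'   `noise_class`.
#' @export
spectral_summary <- function(trace, segment_length = NULL) {
  stopifnot(inherits(trace, "distance_trace"))
  n <- length(trace$values)
  if (is.null(segment_length))
    segment_length <- 2L^floor(log2(min(1024L, n %/% 4L)))
  ac <- autocorrelation(trace)
  hu <- hurst_rs(trace)
  ps <- welch_psd(trace, segment_length = segment_length)
  list(tau_corr = ac$tau_corr, tau0 = ac$tau0, H = hu$H,
       alpha = ps$alpha, noise_class = ps$noise_class)
}
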