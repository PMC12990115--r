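test_that("ACF is normalized and matches the direct lag-sum estimator", {
  set.seed(3)
  x <- rnorm(2048)
  ac <- autocorrelation(x)
  expect_equal(ac$C[1], 1)
  ref <- naive_acf(x, 300)
  expect_equal(ac$C[1:301], ref, tolerance = 1e-8)
  expect_error(autocorrelation(rep(1, 100)), "variance")
  expect_error(autocorrelation(rnorm(8)), "short")
})

test_that("white-noise ACF stays inside the sampling band", {
  set.seed(10)
  n <- 1e5
  ac <- autocorrelation(rnorm(n), max_lag = 100)
  expect_true(all(abs(ac$C[2:101]) < 3 / sqrt(n)))
})

test_that("OU autocorrelation follows the exponential closed form", {
  tauc <- 200
  tr <- gen_ou_trace(0.9, tauc, 0.2, 2^18, 1, seed = 4)
  ac <- autocorrelation(tr)
  lags <- 0:(2 * tauc)
  expect_lt(max(abs(ac$C[lags + 1] - exp(-lags / tauc))), 0.05)
  expect_equal(ac$tau_corr, tauc, tolerance = 0.15)
  expect_lte(ac$tau_corr, ac$tau0)
})

test_that("integrated correlation time of a triangle ACF is T/2", {
  Tz <- 40
  lags <- 0:100
  C <- pmax(1 - lags / Tz, -0.2)
  fake <- structure(list(lags = lags, C = C, tau0 = NA_real_,
                         tau_corr = NA_real_, no_crossing = FALSE),
                    class = "acf_result")
  ic <- integrated_correlation_time(fake, recompute = TRUE)
  expect_equal(attr(ic, "tau0"), Tz)
  expect_equal(as.numeric(ic), Tz / 2, tolerance = 1e-10)
  # no zero crossing: integrate to max lag and flag
  fake2 <- structure(list(lags = 0:50, C = exp(-(0:50) / 200),
                          tau0 = NA_real_, tau_corr = NA_real_,
                          no_crossing = FALSE),
                     class = "acf_result")
  ic2 <- integrated_correlation_time(fake2, recompute = TRUE)
  expect_true(attr(ic2, "no_crossing"))
  expect_equal(attr(ic2, "tau0"), 50)
})

test_that("Hurst estimation recovers known exponents", {
  w <- gen_fgn(0.5, 2^16, seed = 42)
  expect_equal(hurst_rs(w)$H, 0.5, tolerance = 0.05 / 0.5)
  f8 <- gen_fgn(0.8, 2^16, seed = 42)
  expect_equal(hurst_rs(f8)$H, 0.8, tolerance = 0.07 / 0.8)
  expect_error(hurst_rs(rnorm(10)), "short")
  expect_error(hurst_rs(rep(2, 1000)), "constant")
})

test_that("Hurst and PSD estimates are affine invariant", {
  x <- gen_fgn(0.7, 2^14, seed = 6)
  y <- 3.2 * x - 17
  expect_equal(hurst_rs(y)$H, hurst_rs(x)$H, tolerance = 1e-10)
  expect_equal(welch_psd(y, 512)$alpha, welch_psd(x, 512)$alpha,
               tolerance = 1e-8)
})

test_that("Welch spectral exponent separates the three noise regimes", {
  set.seed(19)
  pw <- welch_psd(rnorm(2^16), 1024)
  expect_equal(pw$alpha, 0, tolerance = 0.15)
  expect_equal(pw$noise_class, "white")
  pb <- welch_psd(cumsum(rnorm(2^16)), 1024)
  expect_equal(pb$alpha, 2, tolerance = 0.25 / 2)
  expect_equal(pb$noise_class, "brownian")
  pp <- welch_psd(gen_powerlaw_noise(1.0, 2^16, seed = 3), 1024)
  expect_equal(pp$alpha, 1.0, tolerance = 0.15)
  expect_equal(pp$noise_class, "one_over_f")
  expect_error(welch_psd(rnorm(100), 1024), "short")
})

test_that("noise classification thresholds", {
  expect_equal(classify_noise(0.2), "white")
  expect_equal(classify_noise(1.0), "one_over_f")
  expect_equal(classify_noise(1.9), "brownian")
})

test_that("zero-lag cross-correlation behaves like Pearson r", {
  set.seed(8)
  x <- rnorm(1e5)
  expect_equal(zero_lag_crosscorr(x, x), 1.0)
  expect_equal(zero_lag_crosscorr(x, -x), -1.0)
  expect_lt(abs(zero_lag_crosscorr(x, rnorm(1e5))), 0.01)
  expect_error(zero_lag_crosscorr(x, rep(1, 1e5)), "constant")
  expect_error(zero_lag_crosscorr(x, rnorm(10)), "differ")
})

test_that("spectral summary bundles the indicator set", {
  tr <- gen_ou_trace(0.9, 100, 0.2, 2^13, 1, seed = 9)
  s <- spectral_summary(tr)
  expect_named(s, c("tau_corr", "tau0", "H", "alpha", "noise_class"))
  expect_true(s$alpha > 0.5)  # OU is correlated, not white
})
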