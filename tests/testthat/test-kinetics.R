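test_that("Savitzky-Golay filter reproduces polynomials and cuts noise", {
  t <- 0:200
  cubic <- distance_trace(t, 1 + 0.01 * t - 2e-4 * t^2 + 1e-6 * t^3)
  sm <- smooth_trace(cubic, window = 21, polyorder = 3)
  interior <- 11:190
  expect_equal(sm$values[interior], cubic$values[interior],
               tolerance = 1e-10)
  const <- distance_trace(t, rep(0.9, 201))
  expect_equal(smooth_trace(const, 21, 3)$values, const$values,
               tolerance = 1e-12)
  set.seed(2)
  sine <- sin(2 * pi * t / 100)
  noisy <- distance_trace(t, sine + rnorm(201, 0, 0.1) + 2)
  smn <- smooth_trace(noisy, 21, 3)
  expect_lt(var(smn$values - 2 - sine), var(noisy$values - 2 - sine))
  expect_error(smooth_trace(const, 20, 3), "odd")
  expect_error(smooth_trace(const, 5, 7), "polyorder")
  expect_error(smooth_trace(const, 2001, 3), "length")
})

test_that("contact detection finds downward crossings", {
  tr <- distance_trace(0:6, c(0.6, 0.5, 0.43, 0.50, 0.60, 0.44, 0.60))
  ev <- detect_contacts(tr, 0.45)
  expect_equal(ev$contact_times, c(2, 5))
  expect_equal(ev$intervals, 3)
  expect_equal(ev$n_int, 1)
  # entirely above r
  above <- distance_trace(0:9, seq(0.6, 1.5, length.out = 10))
  expect_equal(detect_contacts(above, 0.45)$n_int, 0)
  expect_length(detect_contacts(above, 0.45)$contact_times, 0)
  # monotone decrease crossing once
  mono <- distance_trace(0:9, seq(1.0, 0.1, length.out = 10))
  evm <- detect_contacts(mono, 0.45)
  expect_length(evm$contact_times, 1)
  expect_equal(evm$n_int, 0)
})

test_that("contact detection is invariant under joint shifts of trace and r", {
  tr <- gen_ou_trace(0.9, 50, 0.2, 5000, 1, seed = 14)
  ev1 <- detect_contacts(tr, 0.45)
  tr2 <- distance_trace(tr$times, tr$values + 1.3, tr$label)
  ev2 <- detect_contacts(tr2, 0.45 + 1.3)
  expect_equal(ev2$contact_times, ev1$contact_times)
})

test_that("programmed telegraph crossings are recovered exactly", {
  # square-ish wave: dips below r at known indices
  v <- rep(0.8, 100)
  dips <- c(20, 45, 90)
  v[dips] <- 0.3
  ev <- detect_contacts(distance_trace(0:99, v), 0.45)
  expect_equal(ev$contact_times, dips - 1)  # times start at 0
})

test_that("MFCT estimator matches closed forms", {
  expect_equal(mfct(rep(6, 10)), 3 / 1000)          # constant c -> c/2
  expect_equal(mfct(c(2, 4)) * 1000, 10 / 6)        # hand arithmetic
  set.seed(77)
  iv <- rexp(1e5, rate = 1 / 8000)                  # mean 8 ns in ps
  expect_equal(mfct(iv), 8, tolerance = 0.02)
  expect_error(mfct(c(5)), "at least 2")
})

test_that("MFCT uncertainty agrees with a bootstrap oracle", {
  expect_equal(mfct_uncertainty(rep(4, 50)), 0)
  set.seed(15)
  iv <- rexp(1e4, rate = 1 / 2000)
  est <- mfct_uncertainty(iv)
  boot <- replicate(1000, {
    s <- sample(iv, replace = TRUE)
    mean(s^2) / (2 * mean(s)) / 1000
  })
  expect_equal(est, sd(boot), tolerance = 0.25)
})

test_that("viscosity correction reproduces the Kramers rescaling", {
  vc <- viscosity_correct(8.64, 1.10, 0.445)
  expect_equal(round(vc$f, 3), 2.472)
  expect_equal(round(vc$t_corr, 2), 21.36)
  expect_equal(round(viscosity_correct(7.12, 1.10, 0.445)$t_corr, 2), 17.60)
  eq <- viscosity_correct(5, 0.9, 0.9)
  expect_equal(eq$f, 1)
  expect_equal(eq$t_corr, 5)
  expect_error(viscosity_correct(5, -1, 0.445), "positive")
  # uncertainties scale by the same factor
  expect_equal(round(0.84 * vc$f, 2), 2.08)
})

test_that("Cauchy-Schwarz bound T >= <delta>/2 holds on random interval sets", {
  set.seed(33)
  for (i in 1:20) {
    iv <- rgamma(200, shape = runif(1, 0.5, 4), rate = 1 / 1000)
    expect_gte(mfct(iv) * 1000, mean(iv) / 2 - 1e-9)
  }
})

test_that("sink-radius optimization recovers a calibrated radius", {
  tr <- smooth_trace(gen_ou_trace(0.65, 200, 0.12, 2e5, 1, seed = 51),
                     51, 3)
  f <- 1.10 / 0.445
  # pre-compute the T(r) curve independently of the optimizer
  t_at <- function(r) mfct(detect_contacts(tr, r)) * f
  t_exp <- t_at(0.47)
  opt <- optimize_sink_radius(tr, t_exp, f, r_min = 0.40, r_max = 0.55,
                              step = 0.001)
  expect_equal(opt$r_opt, 0.47)
  expect_equal(opt$percent_error, 0, tolerance = 1e-10)
  # objective is minimal at r_opt over the returned grid
  g <- opt$grid
  expect_equal(min(g$objective, na.rm = TRUE),
               g$objective[g$r == opt$r_opt])
})

test_that("unreachable experimental time pins the optimum at a boundary", {
  tr <- smooth_trace(gen_ou_trace(0.65, 200, 0.12, 5e4, 1, seed = 52),
                     51, 3)
  opt <- optimize_sink_radius(tr, t_exp = 1e4, f = 2.472)
  expect_true(opt$at_boundary)
  expect_equal(opt$r_opt, 0.40)  # largest T as r decreases
})

test_that("MFCT grows as the sink radius shrinks on an OU trace", {
  tr <- smooth_trace(gen_ou_trace(0.65, 200, 0.12, 2e5, 1, seed = 53),
                     51, 3)
  rs <- c(0.42, 0.45, 0.48, 0.51)
  ts <- vapply(rs, function(r) mfct(detect_contacts(tr, r)), numeric(1))
  expect_true(all(diff(ts) < 0))
})
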