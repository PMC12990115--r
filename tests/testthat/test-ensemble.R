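test_that("single-component fit recovers known parameters", {
  s <- gen_mixture_samples(centers = 0.9, widths = 0.12, weights = 1,
                           n = 20000, seed = 21)
  fit <- fit_ree_distribution(s, n_components = 1)
  expect_equal(fit$components$center, 0.9, tolerance = 0.02 / 0.9)
  expect_equal(fit$components$width, 0.12, tolerance = 0.02 / 0.12)
})

test_that("three components beat two on bimodal data", {
  s <- gen_mixture_samples(centers = c(0.5, 1.2), widths = c(0.08, 0.15),
                           weights = c(0.5, 0.5), n = 20000, seed = 8)
  f3 <- fit_ree_distribution(s, n_components = 3)
  f2 <- fit_ree_distribution(s, n_components = 2)
  expect_lte(f3$residual, f2$residual + 1e-12)
})

test_that("degenerate samples are rejected", {
  expect_error(fit_ree_distribution(rep(0.9, 500)), "variance")
  expect_error(fit_ree_distribution(c(0.5, 0.6)), "at least 100")
})

test_that("fitted mixture density integrates to about 1", {
  s <- gen_mixture_samples(n = 30000, seed = 13)
  fit <- fit_ree_distribution(s)
  grid <- seq(1e-4, max(s) + 0.5, length.out = 4000)
  dens <- skewed_gaussian_density(grid, fit$components$amplitude,
                                  fit$components$center,
                                  fit$components$width)
  integral <- sum(dens) * diff(grid[1:2])
  expect_equal(integral, 1, tolerance = 0.05)
})

test_that("components come back sorted by center", {
  s <- gen_mixture_samples(n = 30000, seed = 13)
  fit <- fit_ree_distribution(s)
  expect_true(!is.unsorted(fit$components$center))
})

test_that("free-energy surface matches the Boltzmann closed form", {
  # all samples in one cell: that cell is 0, everything else masked
  fe1 <- free_energy_surface(rep(0.5, 100), rep(5, 100))
  expect_equal(sum(!is.na(fe1$delta_f)), 1)
  expect_equal(fe1$delta_f[!is.na(fe1$delta_f)], 0)
  # two cells, counts 900/100 at 300 K: ddF = RT ln 9
  fe2 <- free_energy_surface(c(rep(0.5, 900), rep(0.7, 100)),
                             c(rep(5.0, 900), rep(7.0, 100)),
                             temperature = 300)
  occupied <- fe2$delta_f[!is.na(fe2$delta_f)]
  expect_equal(diff(range(occupied)), 8.314462618e-3 * 300 * log(9),
               tolerance = 1e-10)
  # minimum is attained by the most-populated cell
  expect_equal(which.min(fe2$delta_f), which.max(fe2$counts))
  expect_true(all(occupied >= 0))
})

test_that("free-energy surface is uniform for uniform occupancy and
           invariant under sample duplication", {
  # exactly uniform occupancy: one sample per cell center -> all dF equal
  cent <- expand.grid(rg = seq(0.45, 0.75, length.out = 4),
                      sasa = seq(5.5, 9.5, length.out = 4))
  feu <- free_energy_surface(rep(cent$rg, 10), rep(cent$sasa, 10), bins = 4)
  occ <- feu$delta_f[!is.na(feu$delta_f)]
  expect_equal(diff(range(occ)), 0, tolerance = 1e-12)
  # duplication invariance on irregular data
  set.seed(2)
  rg <- runif(4000, 0.4, 0.8)
  sasa <- runif(4000, 5, 10)
  fe <- free_energy_surface(rg, sasa, bins = 4)
  fe2 <- free_energy_surface(c(rg, rg), c(sasa, sasa), bins = 4)
  expect_equal(fe2$delta_f, fe$delta_f, tolerance = 1e-12)
})

test_that("block averaging: constant, i.i.d. and correlated regimes", {
  expect_equal(block_average_error(rep(3.7, 100))$error, 0)
  set.seed(5)
  n <- 2e4
  ba <- block_average_error(rnorm(n))
  expect_equal(ba$error, 1 / sqrt(n), tolerance = 0.30)
  # OU with tau_c = 100 dt: plateau error ~ sqrt(2 tau_c) x naive
  tr <- gen_ou_trace(10, 100, 1, 1e5, 1, seed = 6)
  bo <- block_average_error(tr$values)
  ratio <- bo$error / (sd(tr$values) / sqrt(1e5))
  expect_gt(ratio, sqrt(200) / 2)
  expect_lt(ratio, sqrt(200) * 2)
})
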