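test_that("multi-model PDB round trip preserves frames and times", {
  bc <- gen_bead_chain(n_beads = 5, n_frames = 3, dt = 2, seed = 3)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_frames_pdb(bc$frames, path)
  rd <- read_trajectory(path, dt = 2)
  expect_equal(rd$times, c(0, 2, 4))
  expect_equal(nrow(rd$xyz), 3)
  # PDB stores 3 decimals in Angstrom -> 5e-5 nm rounding
  expect_lt(max(abs(rd$xyz - bc$frames$xyz)), 1e-4)
})

test_that("trajectory reader rejects bad inputs", {
  expect_error(read_trajectory(file.path(tempdir(), "nope.pdb")),
               "unreadable")
  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", empty)
  expect_error(read_trajectory(empty))
  # atom-count mismatch against a topology
  bc3 <- gen_bead_chain(n_beads = 5, n_frames = 2, seed = 1)
  bc4 <- gen_bead_chain(n_beads = 6, n_frames = 1, seed = 1)
  p3 <- withr::local_tempfile(fileext = ".pdb")
  p4 <- withr::local_tempfile(fileext = ".pdb")
  write_frames_pdb(bc3$frames, p3)
  write_frames_pdb(bc4$frames, p4)
  expect_error(read_trajectory(p3, topology_path = p4), "mismatch")
})

test_that("end-to-end distance is the midpoint-to-midpoint distance", {
  co <- rbind(c(0, 0, 0), c(0, 0, 0.2), c(0, 0, 1.0), c(0, 0, 1.2))
  lab <- label_map(c(1, 2), c(3, 4), c(1, 2), c(3, 4), c(1, 4), 1:4,
                   rep(1, 4))
  expect_equal(end_to_end_distance(co, lab), 1.0)
  # coincident midpoints
  co2 <- rbind(c(0, 0, 0), c(0, 0, 0.2), c(0, 0, -0.1), c(0, 0, 0.3))
  expect_equal(end_to_end_distance(co2, lab), 0.0)
  # random frame vs independent arithmetic
  set.seed(9)
  co3 <- matrix(rnorm(12), 4, 3)
  m1 <- (co3[1, ] + co3[2, ]) / 2
  m2 <- (co3[3, ] + co3[4, ]) / 2
  expect_equal(end_to_end_distance(co3, lab), sqrt(sum((m1 - m2)^2)),
               tolerance = 1e-12)
})

test_that("C-alpha distance and radius of gyration match hand values", {
  co <- rbind(c(0, 0, 0), c(0.1, 0, 0), c(0.2, 0, 0), c(0.38, 0, 0))
  lab <- label_map(c(1, 2), c(3, 4), c(1, 2), c(3, 4), c(1, 4), 1:4,
                   rep(1, 4))
  expect_equal(ca_ca_distance(co, lab), 0.38)
  expect_equal(ca_ca_distance(co[c(1, 1, 1, 1), ], lab), 0.0)
  # two equal masses 1 nm apart -> Rg = 0.5
  co2 <- rbind(c(0, 0, 0), c(1, 0, 0))
  lab2 <- label_map(c(1, 2), c(1, 2), c(1, 2), c(1, 2), c(1, 2), 1:2,
                    c(2, 2))
  expect_equal(radius_of_gyration(co2, lab2), 0.5)
  # single positive-mass atom -> 0
  lab1 <- label_map(c(1, 2), c(1, 2), c(1, 2), c(1, 2), c(1, 2), 1,
                    c(3, 0))
  expect_equal(radius_of_gyration(co2[1:2, ], lab1), 0.0)
  # random 10-atom frame vs direct-sum oracle
  set.seed(4)
  co10 <- matrix(rnorm(30), 10, 3)
  m <- runif(10, 0.5, 16)
  lab10 <- label_map(c(1, 2), c(9, 10), c(1, 2), c(9, 10), c(1, 10),
                     1:10, m)
  com <- colSums(co10 * m) / sum(m)
  rg_ref <- sqrt(sum(m * rowSums(sweep(co10, 2, com)^2)) / sum(m))
  expect_equal(radius_of_gyration(co10, lab10), rg_ref, tolerance = 1e-12)
})

test_that("geometric observables are invariant under rigid motion", {
  set.seed(12)
  co <- matrix(rnorm(24), 8, 3)
  lab <- simple_labels(8, masses = runif(8, 1, 12))
  co2 <- rigid_transform(co, seed = 5)
  expect_equal(end_to_end_distance(co2, lab), end_to_end_distance(co, lab),
               tolerance = 1e-10)
  expect_equal(ca_ca_distance(co2, lab), ca_ca_distance(co, lab),
               tolerance = 1e-10)
  expect_equal(radius_of_gyration(co2, lab), radius_of_gyration(co, lab),
               tolerance = 1e-10)
})

test_that("kappa-squared reproduces the closed-form geometries", {
  z <- c(0, 0, 1); x <- c(1, 0, 0); y <- c(0, 1, 0)
  expect_equal(kappa_squared(z, z, z), 4.0)       # collinear maximum
  expect_equal(kappa_squared(x, x, z), 1.0)       # parallel, perp to ree
  expect_equal(kappa_squared(x, y, z), 0.0)       # fully orthogonal
  expect_error(kappa_squared(2 * x, y, z), "unit")
})

test_that("kappa-squared is bounded, even under dipole inversion", {
  set.seed(31)
  for (i in 1:200) {
    v <- function() { u <- rnorm(3); u / sqrt(sum(u^2)) }
    d <- v(); a <- v(); r <- v()
    k <- kappa_squared(d, a, r)
    expect_gte(k, 0)
    expect_lte(k, 4)
    expect_equal(kappa_squared(-d, a, r), k)
    expect_equal(kappa_squared(d, -a, r), k)
  }
})

test_that("extract_traces equals frame-by-frame scalar calls exactly", {
  bc <- gen_bead_chain(n_beads = 6, n_frames = 50, seed = 11)
  tr <- extract_traces(bc$frames, bc$labels)
  expect_length(tr$ree$values, 50)
  for (i in c(1, 17, 50)) {
    co <- frame_coords(bc$frames, i)
    expect_identical(tr$ree$values[i], end_to_end_distance(co, bc$labels))
    expect_identical(tr$caca$values[i], ca_ca_distance(co, bc$labels))
    expect_identical(tr$rg$values[i], radius_of_gyration(co, bc$labels))
  }
  # constant coordinates give constant traces
  const <- md_frames(matrix(rep(bc$frames$xyz[1, ], 5), 5, byrow = TRUE),
                     0:4)
  trc <- extract_traces(const, bc$labels)
  expect_equal(diff(range(trc$ree$values)), 0)
  expect_equal(diff(range(trc$rg$values)), 0)
})
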