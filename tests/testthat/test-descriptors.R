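test_that("proton-transfer coordinate reproduces distances and antisymmetry", {
  g <- geometry(c("O", "H", "O"),
                rbind(c(0, 0, 0), c(1.0, 0, 0), c(2.45, 0, 0)))
  expect_equal(proton_transfer_coordinate(g, 1, 2, 3), 1.0 - 1.45)
  # equidistant proton
  gm <- toy_geometry(delta = 0)
  at <- attr(gm, "atoms")
  expect_equal(proton_transfer_coordinate(gm, at$o1, at$h, at$o2), 0,
               tolerance = 1e-12)
  set.seed(8)
  for (i in 1:10) {
    gr <- geometry(c("O", "H", "O"), matrix(rnorm(9), 3, 3))
    expect_equal(proton_transfer_coordinate(gr, 1, 2, 3),
                 -proton_transfer_coordinate(gr, 3, 2, 1), tolerance = 1e-12)
  }
  expect_error(proton_transfer_coordinate(g, 1, 1, 3), "distinct")
  expect_error(proton_transfer_coordinate(g, 1, 2, 9), "out of range")
})

test_that("free-energy estimator recovers a harmonic well and stays flat on uniform data", {
  set.seed(15)
  k <- 2.0
  x <- rnorm(1e5, 0, sqrt(kT300 / k))
  prof <- free_energy_profile(x, temperature = 300, units = "eV")
  # quadratic fit near the minimum
  sel <- which(!is.na(prof$free_energy) & abs(prof$bin_centers) <
                 2 * sqrt(kT300 / k))
  fit <- lm(prof$free_energy[sel] ~ I(prof$bin_centers[sel]^2))
  expect_equal(2 * unname(coef(fit)[2]), k, tolerance = 0.10)
  expect_equal(classify_wells(prof)$wells, "single")
  expect_equal(min(prof$free_energy, na.rm = TRUE), 0)
  # uniform samples give a flat profile up to bin noise (interior bins only:
  # the 5 percent range padding leaves partially covered edge bins)
  u <- runif(1e5)
  pu <- free_energy_profile(u, temperature = 300)
  interior <- pu$bin_centers > 0.02 & pu$bin_centers < 0.98
  se <- 1 / sqrt(1e5 / 50)       # kT units, per-bin standard error
  expect_lt(max(pu$free_energy[interior], na.rm = TRUE), 3 * se + 0.05)
  expect_error(free_energy_profile(numeric(0)), "at least 1000")
})

test_that("estimator error shrinks with more samples", {
  k <- 1.5
  curv_err <- function(n, seed) {
    set.seed(seed)
    x <- rnorm(n, 0, sqrt(kT300 / k))
    prof <- free_energy_profile(x, temperature = 300, units = "eV")
    sel <- which(!is.na(prof$free_energy) &
                   abs(prof$bin_centers) < 2 * sqrt(kT300 / k))
    fit <- lm(prof$free_energy[sel] ~ I(prof$bin_centers[sel]^2))
    abs(2 * unname(coef(fit)[2]) - k) / k
  }
  e4 <- mean(vapply(1:4, function(s) curv_err(1e4, s), numeric(1)))
  e5 <- mean(vapply(1:4, function(s) curv_err(1e5, s + 100), numeric(1)))
  expect_lt(e5, e4)
})

test_that("Boltzmann sampling of a quartic double well yields a symmetric two-well profile", {
  barrier <- 3 * kT300
  dm <- 0.5
  b <- 2 * barrier / dm^2; a <- b / (2 * dm^2)
  V <- function(x) a * x^4 - b * x^2
  set.seed(23)
  x <- metropolis_sample(V, 1e5, temperature = 300, x0 = dm, step = 0.25)
  prof <- free_energy_profile(x, temperature = 300, units = "eV")
  cl <- classify_wells(prof)
  expect_equal(cl$wells, "double")
  expect_equal(cl$barrier, barrier, tolerance = 0.15)
  expect_equal(sort(cl$minima), c(-dm, dm), tolerance = 0.15)
  # symmetry within noise
  f <- prof$free_energy
  mirrored <- rev(f)
  ok <- !is.na(f) & !is.na(mirrored)
  expect_lt(median(abs(f[ok] - mirrored[ok])), 0.6 * kT300)
})

test_that("a planar pentagon has zero deplanarization; an envelope matches the torsion oracle", {
  g <- toy_geometry(q = 0)
  expect_equal(ring_deplanarization(g, 1:5), 0, tolerance = 1e-9)
  # envelope: atom 3 of a unit-edge regular pentagon lifted 0.5 out of plane
  r <- 1 / (2 * sin(pi / 5))
  ang <- 2 * pi * (0:4) / 5
  coords <- cbind(r * cos(ang), r * sin(ang), c(0, 0, 0.5, 0, 0))
  ge <- geometry(rep("C", 5), coords)
  expected <- 0
  for (k in 0:4) {
    idx <- ((k + 0:3) %% 5) + 1
    expected <- expected + abs(torsion_oracle(coords[idx[1], ], coords[idx[2], ],
                                              coords[idx[3], ], coords[idx[4], ]))
  }
  expect_equal(ring_deplanarization(ge, 1:5), expected, tolerance = 1e-6)
  expect_gt(expected, 10)   # a 0.5-Angstrom pucker is far from planar
  # rigid-motion invariance
  set.seed(5)
  for (i in 1:5) {
    gr <- random_rigid_motion(ge)
    expect_equal(ring_deplanarization(gr, 1:5),
                 ring_deplanarization(ge, 1:5), tolerance = 1e-9)
  }
  # collinear triple is reported with the offending atoms
  bad <- geometry(rep("C", 5),
                  rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0),
                        c(1, 2, 0)))
  expect_error(ring_deplanarization(bad, 1:5), "collinear")
})

test_that("descriptors are invariant under rigid motion of the geometry", {
  set.seed(12)
  g <- toy_geometry(delta = -0.2, q = 0.3)
  at <- attr(g, "atoms")
  for (i in 1:5) {
    gr <- random_rigid_motion(g)
    expect_equal(proton_transfer_coordinate(gr, at$o1, at$h, at$o2),
                 proton_transfer_coordinate(g, at$o1, at$h, at$o2),
                 tolerance = 1e-9)
    expect_equal(atom_distance(gr, at$carbonyl_c, at$carbonyl_o),
                 atom_distance(g, at$carbonyl_c, at$carbonyl_o),
                 tolerance = 1e-9)
  }
})

test_that("bond-length series and histogram behave on static and dynamic input", {
  gs <- replicate(20, geometry(c("C", "O"),
                               rbind(c(0, 0, 0), c(1.23, 0, 0))),
                  simplify = FALSE)
  bl <- bond_length_series(gs, 1, 2)
  expect_true(all(abs(bl$series - 1.23) < 1e-12))
  expect_equal(sum(bl$mass), 1, tolerance = 1e-12)
  expect_error(bond_length_series(gs, 1, 7), "out of range")
  # decaying (long-HB) excited condition shows a carbonyl mode shifted
  # upward relative to the short-bond condition
  e25 <- run_condition(2.5, n_replicas = 1L, equil_fs = 1000,
                       excited_fs = 1000, seed_base = 1001L)
  e45 <- run_condition(4.5, n_replicas = 1L, equil_fs = 1000,
                       excited_fs = 1000, seed_base = 4001L)
  at <- attr(toy_geometry(), "atoms")
  b25 <- bond_length_series(e25$trajectories[[1]], at$carbonyl_c, at$carbonyl_o)
  b45 <- bond_length_series(e45$trajectories[[1]], at$carbonyl_c, at$carbonyl_o)
  expect_gt(b45$mode - b25$mode, 0.03)
  expect_lt(b45$mode - b25$mode, 0.25)
  expect_equal(sum(b45$mass), 1, tolerance = 1e-12)
})

test_that("hydrogen-bond enumeration finds, flags and sorts donor-acceptor pairs", {
  two_o <- geometry(c("O", "O"), rbind(c(0, 0, 0), c(2.45, 0, 0)))
  hb <- hb_distances(two_o)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$distance, 2.45, tolerance = 1e-12)
  expect_true(hb$shb)
  far <- geometry(c("O", "O"), rbind(c(0, 0, 0), c(4.0, 0, 0)))
  expect_equal(nrow(hb_distances(far)), 0L)
  expect_error(hb_distances(geometry("C", matrix(0, 1, 3))), "no atoms")
  # synthetic short-hydrogen-bond dimer fixture
  fx <- system.file("extdata", "shb_dimer_synthetic.xyz", package = "shbdyn")
  g <- read_geometry(fx)
  hb <- hb_distances(g)
  expect_equal(hb$distance[1], 2.45, tolerance = 1e-6)
  expect_true(hb$shb[1])
  expect_true(all(diff(hb$distance) >= 0))
})
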