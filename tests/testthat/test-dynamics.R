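test_that("thermostatted sampling satisfies equipartition at 300 K", {
  s <- build_surface(2.5)
  g <- sample_ground_trajectory(s, temperature = 300, dt = 0.5,
                                n_steps = 100000L, seed = 7, tau = 10)
  ke <- kinetic_energy(g)
  burn <- 2000
  mean_ke_dof <- mean(ke[burn:length(ke)]) / 2
  expect_equal(mean_ke_dof, kT300 / 2, tolerance = 0.05)
})

test_that("kinetic-energy distribution matches the canonical chi-squared form", {
  s <- build_surface(2.5)
  g <- sample_ground_trajectory(s, temperature = 300, dt = 0.5,
                                n_steps = 600000L, seed = 13, tau = 5)
  ke <- kinetic_energy(g)
  # decorrelated samples: every 60 fs (120 steps) after burn-in; the total
  # KE of 2 DOF is exponential with mean kT
  samp <- ke[seq(4000, length(ke), by = 120)]
  ks <- suppressWarnings(stats::ks.test(samp, "pexp", rate = 1 / kT300))
  expect_gt(ks$p.value, 0.01)
})

test_that("position distribution in the harmonic mode is Boltzmann", {
  s <- build_surface(2.5)
  g <- sample_ground_trajectory(s, temperature = 300, dt = 0.5,
                                n_steps = 200000L, seed = 21, tau = 10)
  vq <- var(g$q[2000:length(g$q)])
  expect_equal(vq, kT300 / s$params$k_q_ground, tolerance = 0.10)
})

test_that("a system started at rest at the minimum stays put without a thermostat", {
  s <- build_surface(2.5)
  # locate the exact ground-adiabat minimum (slightly off the diabatic well)
  opt <- optim(c(s$params$delta_well, 0), function(x)
    adiabatic_energies(s, x[1], x[2])$E0, method = "BFGS",
    control = list(reltol = 1e-14))
  g <- sample_ground_trajectory(s, thermostat = FALSE, n_steps = 200L,
                                init = list(delta = opt$par[1], q = opt$par[2],
                                            v_delta = 0, v_q = 0))
  expect_lt(max(abs(g$delta - opt$par[1])), 1e-5)
  expect_lt(max(abs(g$q - opt$par[2])), 1e-5)
})

test_that("excited propagation has the documented frame count and ordered states", {
  s <- build_surface(3.0)
  g <- sample_ground_trajectory(s, n_steps = 2000L, seed = 5)
  ex <- run_excited_trajectory(s, trajectory_frame(g), duration = 1000,
                               dt = 0.5, seed = 6)
  expect_length(ex$times, 2001L)                 # 2000 steps, 2001 frames
  expect_equal(diff(ex$times), rep(0.5, 2000), tolerance = 1e-12)
  expect_true(all(ex$E_S1 >= ex$E_S0))
  expect_gte(min(ex$E_S1 - ex$E_S0), 2 * s$coupling - 1e-12)
  expect_error(run_excited_trajectory(s, trajectory_frame(g), duration = 1000.3,
                                      dt = 0.5), "integral")
})

test_that("trajectories are bit-identical under a fixed seed", {
  s <- build_surface(3.5)
  g1 <- sample_ground_trajectory(s, n_steps = 500L, seed = 42)
  g2 <- sample_ground_trajectory(s, n_steps = 500L, seed = 42)
  expect_identical(g1$delta, g2$delta)
  expect_identical(g1$v_q, g2$v_q)
})

test_that("a restrained coordinate stays near its target", {
  s <- build_surface(3.0)
  g <- sample_ground_trajectory(s, n_steps = 2000L, seed = 9)
  ex <- run_excited_trajectory(s, trajectory_frame(g), duration = 2000,
                               dt = 0.5, seed = 10,
                               restraints = list(list(coordinate = "q",
                                                      target = 0.3, k = 10)))
  qs <- ex$q[1000:length(ex$q)]
  expect_lt(abs(mean(qs) - 0.3), sd(qs))
  expect_error(run_excited_trajectory(s, trajectory_frame(g), duration = 10,
                                      restraints = list(list(coordinate = "phi",
                                                             target = 0))),
               "unknown coordinate")
})

test_that("analytic coupling vanishes at rest, is linear in velocity, and matches finite differences", {
  s <- build_surface(3.0)
  frame <- list(delta = 0.2, q = 0.4, v_delta = 0, v_q = 0)
  expect_identical(analytic_nac(s, frame), 0)
  f1 <- list(delta = 0.2, q = 0.4, v_delta = 0.01, v_q = -0.02)
  f2 <- list(delta = 0.2, q = 0.4, v_delta = 0.02, v_q = -0.04)
  expect_equal(analytic_nac(s, f2), 2 * analytic_nac(s, f1), tolerance = 1e-12)
  set.seed(31)
  for (i in 1:20) {
    fr <- list(delta = runif(1, -0.5, 0.5), q = runif(1, -0.3, 1.2),
               v_delta = runif(1, -0.03, 0.03), v_q = runif(1, -0.03, 0.03))
    a <- analytic_nac(s, fr)
    f <- fd_nac(s, fr, dt = 0.05)
    if (abs(a) > 1e-8) expect_equal(f, a, tolerance = 0.01)
  }
})

test_that("the coupling is small when the gap is huge", {
  # identical nuclear motion evaluated on a near-degenerate surface (diabats
  # crossing inside the visited region) vs a far-detuned one (huge gap
  # everywhere, large c)
  s <- build_surface(3.5)
  g <- sample_ground_trajectory(s, n_steps = 2000L, seed = 3)
  ex <- run_excited_trajectory(s, trajectory_frame(g), duration = 500,
                               dt = 0.5, seed = 4)
  frames <- lapply(seq(1, length(ex$times), by = 10), function(i)
    list(delta = ex$delta[i], q = ex$q[i],
         v_delta = ex$v_delta[i], v_q = ex$v_q[i]))
  near_degen <- build_surface(3.5, surface_params(gap0 = 1.1))
  far <- build_surface(3.5, surface_params(gap0 = 40, coupling = 1))
  s_near <- vapply(frames, function(fr) abs(analytic_nac(near_degen, fr)),
                   numeric(1))
  s_far <- vapply(frames, function(fr) abs(analytic_nac(far, fr)), numeric(1))
  expect_lt(max(s_far), 1e-3 * max(s_near))
})
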