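test_that("decoupled states keep their populations and acquire the exact phase", {
  hbar <- const$hbar_ev_fs
  tt <- seq(0, 100, by = 0.5)
  tr <- electronic_trajectory(tt, rep(0, length(tt)), rep(3, length(tt)),
                              rep(0, length(tt)))
  a <- propagate_amplitudes(tr)
  expect_lt(max(abs(a$pop_S1 - 1)), 1e-12)
  expect_lt(max(Mod(a$C_S1 - exp(-1i * 3 * tt / hbar))), 1e-9)
  expect_error(propagate_amplitudes(tr, init = c(0.5 + 0i, 0.5 + 0i)),
               "not normalized")
})

test_that("constant gap and coupling reproduce the closed-form Rabi solution", {
  hbar <- const$hbar_ev_fs
  e0 <- 0.2; e1 <- 1.1; sg <- 0.02
  tt <- seq(0, 400, by = 0.5)
  tr <- electronic_trajectory(tt, rep(e0, length(tt)), rep(e1, length(tt)),
                              rep(sg, length(tt)))
  a <- propagate_amplitudes(tr, n_substeps = 256L)
  # independent closed form: eigen-decomposition of the constant generator
  G <- matrix(c(-1i * e0 / hbar, sg, -sg, -1i * e1 / hbar), 2, 2)
  eg <- eigen(G)
  sol <- t(vapply(tt, function(t)
    as.vector(eg$vectors %*% diag(exp(eg$values * t)) %*%
                solve(eg$vectors, c(0, 1))), complex(2)))
  expect_lt(max(abs(a$pop_S0 - Mod(sol[, 1])^2)), 1e-6)
  expect_lt(max(abs(a$pop_S1 - Mod(sol[, 2])^2)), 1e-6)
  expect_lt(max(Mod(a$C_S0 - sol[, 1])), 1e-6)
  expect_lt(max(Mod(a$C_S1 - sol[, 2])), 1e-6)
})

test_that("amplitude norm is conserved along surrogate trajectories", {
  s <- build_surface(3.5)
  g <- sample_ground_trajectory(s, n_steps = 2000L, seed = 17)
  ex <- run_excited_trajectory(s, trajectory_frame(g), duration = 1000,
                               dt = 0.5, seed = 18)
  a <- propagate_amplitudes(ex)
  expect_lt(a$norm_error, 1e-8)
})

test_that("per-step probability vanishes without coupling or ground amplitude", {
  tt <- seq(0, 10, by = 0.5)
  n <- length(tt)
  tr <- electronic_trajectory(tt, rep(0, n), rep(3, n), rep(0, n))
  a <- propagate_amplitudes(tr)
  expect_true(all(step_nrp(a, tr$sigma) == 0))       # C_S0 = 0 throughout
  # nonzero ground amplitude but zero coupling
  a2 <- a; a2$C_S0 <- rep(0.6 + 0i, n); a2$C_S1 <- rep(0.8 + 0i, n)
  a2$pop_S0 <- rep(0.36, n); a2$pop_S1 <- rep(0.64, n)
  expect_true(all(step_nrp(a2, rep(0, n)) == 0))
})

test_that("negative raw flux is clamped to zero and both normalizations work", {
  # constant product C_S1 C_S0* sigma chosen so the raw expression is negative
  tt <- c(0, 0.5, 1)
  a <- structure(list(times = tt,
                      C_S0 = rep(sqrt(0.2) + 0i, 3),
                      C_S1 = rep(sqrt(0.8) + 0i, 3),
                      pop_S0 = rep(0.2, 3), pop_S1 = rep(0.8, 3)),
                 class = "amplitude_series")
  sig_pos <- rep(0.1, 3)    # Re[C1 C0*] sigma > 0 -> raw NRP < 0 -> clamp
  expect_true(all(step_nrp(a, sig_pos) == 0))
  expect_true(all(step_nrp(a, sig_pos, clamp = FALSE) < 0))
  raw_s1 <- step_nrp(a, -sig_pos)
  raw_s0 <- step_nrp(a, -sig_pos, normalize = "s0")
  expect_equal(raw_s0 / raw_s1, rep(0.8 / 0.2, 2), tolerance = 1e-12)
  a$pop_S1 <- rep(1e-13, 3)
  expect_error(step_nrp(a, sig_pos), "below 1e-12")
})

test_that("the accumulation recursion equals the closed product form", {
  set.seed(101)
  for (rep in 1:20) {
    nrp <- runif(200, 0, 0.05)
    prof <- accumulate_decay(nrp)
    product_form <- 1 - cumprod(1 - nrp)       # independent oracle
    expect_lt(max(abs(prof$anrp[-1] - product_form)), 1e-12)
    expect_equal(prof$anrp[1], 0)
    expect_true(all(diff(prof$anrp) >= 0))
    expect_true(all(prof$anrp >= 0 & prof$anrp <= 1))
    expect_equal(prof$hazard, (1 - prof$anrp[-length(prof$anrp)]) * nrp,
                 tolerance = 1e-15)
  }
  # constant-p closed form
  p <- 0.01; n <- 150
  prof <- accumulate_decay(rep(p, n))
  expect_equal(prof$anrp[n + 1], 1 - (1 - p)^n, tolerance = 1e-12)
  expect_true(all(accumulate_decay(rep(0, 50))$anrp == 0))
  expect_error(accumulate_decay(c(0.1, 1.2)), "must lie in")
  expect_error(accumulate_decay(c(0.1, -0.01)), "must lie in")
})

test_that("a replica ensemble is deterministic and mean lies inside the replica envelope", {
  e1 <- run_condition(3.0, n_replicas = 2L, equil_fs = 500, excited_fs = 250,
                      seed_base = 77L)
  e2 <- run_condition(3.0, n_replicas = 2L, equil_fs = 500, excited_fs = 250,
                      seed_base = 77L)
  expect_identical(e1$anrp_mean, e2$anrp_mean)
  expect_true(all(e1$anrp_mean >= e1$anrp_min - 1e-15))
  expect_true(all(e1$anrp_mean <= e1$anrp_max + 1e-15))
  expect_length(e1$profiles[[1]]$nrp, 500L)
  expect_error(run_condition(3.0, n_replicas = 0L), "n_replicas")
})

test_that("the excited-state gap of the short-bond dimer sits in the visible window", {
  e <- run_condition(2.5, n_replicas = 2L, equil_fs = 1500, excited_fs = 1000,
                     seed_base = 11L)
  gaps <- unlist(lapply(e$trajectories, function(tr) tr$E_S1 - tr$E_S0))
  expect_lt(abs(mean(gaps) - surface_params()$gap_target), 0.5)
})
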