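# Independent oracles and fixture builders used across the test files.

const <- shb_constants()
kT300 <- const$kb_ev_k * 300

# Finite-difference nonadiabatic coupling from eigenvector overlap:
# sigma ~ <phi0(t) | phi1(t + dt)> / dt with sign-continuous eigenvectors.
fd_nac <- function(surface, frame, dt = 0.05) {
  eigvecs <- function(delta, q) {
    v <- diabats(surface, delta, q)
    H <- matrix(c(v$V1, surface$coupling, surface$coupling, v$V2), 2, 2)
    e <- eigen(H, symmetric = TRUE)
    ord <- order(e$values)          # phi0 = lower state
    vec <- e$vectors[, ord]
    # fix gauge: positive first component
    for (k in 1:2) if (vec[1, k] < 0) vec[, k] <- -vec[, k]
    vec
  }
  v1 <- eigvecs(frame$delta, frame$q)
  v2 <- eigvecs(frame$delta + frame$v_delta * dt, frame$q + frame$v_q * dt)
  sum(v1[, 1] * v2[, 2]) / dt
}

# Linear-sweep avoided crossing as an electronic trajectory: diabats with
# relative slope dk cross at x = 0, traversed at constant velocity v.
linear_sweep_traj <- function(cpl, dk, v, x_max = 3, dt = 0.05) {
  tt <- seq(0, 2 * x_max / v, by = dt)
  x <- -x_max + v * tt
  D <- dk * x
  rt <- sqrt(D^2 + 4 * cpl^2)
  sig <- -cpl * (dk * v) / (D^2 + 4 * cpl^2)
  electronic_trajectory(tt, -rt / 2, rt / 2, sig)
}

# Dense-output integration of the same interaction-picture amplitude ODE the
# package solves, via deSolve::zvode at tight tolerance.
ode_oracle_amplitudes <- function(traj, init = c(0 + 0i, 1 + 0i),
                                  rtol = 1e-12, atol = 1e-13) {
  hbar <- const$hbar_ev_fs
  tt <- traj$times; n <- length(tt); dt <- traj$dt
  gk <- (traj$E_S1 - traj$E_S0) / hbar
  sk <- traj$sigma
  phi_k <- c(0, cumsum(0.5 * (gk[-1] + gk[-n]) * dt))
  rhs <- function(t, y, p) {
    k <- min(max(1L, findInterval(t, tt)), n - 1L)
    tau <- t - tt[k]
    sg <- sk[k] + (sk[k + 1] - sk[k]) * tau / dt
    ph <- phi_k[k] + gk[k] * tau + 0.5 * (gk[k + 1] - gk[k]) * tau^2 / dt
    e <- exp(1i * ph)
    list(c(-sg * Conj(e) * y[2], sg * e * y[1]))
  }
  out <- deSolve::zvode(init, times = tt, func = rhs, parms = NULL,
                        rtol = rtol, atol = atol)
  w0 <- traj$E_S0 / hbar; w1 <- traj$E_S1 / hbar
  P0 <- c(0, cumsum(0.5 * (w0[-1] + w0[-n]) * dt))
  P1 <- c(0, cumsum(0.5 * (w1[-1] + w1[-n]) * dt))
  list(C_S0 = out[, 2] * exp(-1i * P0), C_S1 = out[, 3] * exp(-1i * P1))
}

# Metropolis sampler for a 1-D Boltzmann density exp(-V(x)/kT).
metropolis_sample <- function(V, n, temperature = 300, x0 = 0, step = 0.1,
                              thin = 5L) {
  kT <- const$kb_ev_k * temperature
  x <- numeric(n)
  cur <- x0; vcur <- V(cur)
  for (i in seq_len(n * thin)) {
    prop <- cur + runif(1, -step, step)
    vp <- V(prop)
    if (vp <= vcur || runif(1) < exp(-(vp - vcur) / kT)) {
      cur <- prop; vcur <- vp
    }
    if (i %% thin == 0L) x[i / thin] <- cur
  }
  x
}

# Independent torsion evaluation (Gram-Schmidt / projection formulation,
# distinct from the atan2 cross-product formula in the package): angle
# between p1-p2 and p4-p3 projected onto the plane normal to the axis.
torsion_oracle <- function(p1, p2, p3, p4) {
  b1 <- p1 - p2; b2 <- p3 - p2; b3 <- p4 - p3
  u2 <- b2 / sqrt(sum(b2^2))
  v1 <- b1 - sum(b1 * u2) * u2
  v3 <- b3 - sum(b3 * u2) * u2
  cosphi <- sum(v1 * v3) / sqrt(sum(v1^2) * sum(v3^2))
  phi <- acos(pmin(pmax(cosphi, -1), 1)) * 180 / pi
  s <- sign(sum(cross3(v1, v3) * u2))
  if (s == 0) s <- 1
  -s * phi
}
cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

# Random rigid motion applied to a geometry.
random_rigid_motion <- function(geom) {
  th <- runif(3, 0, 2 * pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), sin(th[1]), 0, -sin(th[1]), cos(th[1])), 3, 3)
  Ry <- matrix(c(cos(th[2]), 0, -sin(th[2]), 0, 1, 0, sin(th[2]), 0, cos(th[2])), 3, 3)
  Rz <- matrix(c(cos(th[3]), sin(th[3]), 0, -sin(th[3]), cos(th[3]), 0, 0, 0, 1), 3, 3)
  R <- Rx %*% Ry %*% Rz
  tr <- runif(3, -5, 5)
  g2 <- geom
  g2$coords <- sweep(geom$coords %*% t(R), 2, -tr)
  g2
}

# Gauss-Hermite quadrature overlap oracle for Franck-Condon factors
# (independent of the package's trapezoid implementation).
gh_fc_oracle <- function(mode, v_excited, v_ground, n_nodes = 120L) {
  gh <- pracma::gaussHermite(n_nodes)
  wr <- mode$freq_excited / mode$freq_ground
  d <- mode$displacement
  hermite_psi <- function(v, x) {
    p0 <- pi^(-0.25) * exp(-x^2 / 2)
    if (v == 0) return(p0)
    p1 <- sqrt(2) * x * p0
    if (v == 1) return(p1)
    for (n in 2:v) {
      p2 <- sqrt(2 / n) * x * p1 - sqrt((n - 1) / n) * p0
      p0 <- p1; p1 <- p2
    }
    p1
  }
  x <- gh$x
  # integrand with the e^{-x^2} weight factored out
  f <- hermite_psi(v_ground, x) * wr^(0.25) *
    hermite_psi(v_excited, sqrt(wr) * (x - d)) * exp(x^2)
  sum(gh$w * f)^2
}
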