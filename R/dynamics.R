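# Classical propagation on the model surfaces: velocity-Verlet integrator with
# a stochastic velocity-rescaling (canonical sampling) thermostat, emitting
# electronic frames (E_S0, E_S1, nonadiabatic coupling, oscillator strength)
# at every step.

# Core integrator. state = "ground" propagates on E0, "excited" on E1.
# restraints: list of list(coordinate = "delta"|"q", target, k).
# Returns the trajectory record as a list of vectors.
md_core <- function(surface, x0, v0, n_steps, dt, temperature, tau,
                    thermostat, state, restraints = NULL) {
  p <- surface$params
  kb <- .kc$kb_ev_k; acc <- .kc$acc_ev_ang_amu
  a4 <- surface$quartic_a; b2 <- surface$quartic_b
  kq1 <- p$k_q_ground; k2 <- p$k_delta_excited
  gap0 <- p$gap0; g <- p$gap_coupling; st <- surface$stiffening
  cc <- surface$coupling; c4 <- 4 * cc^2
  excited <- identical(state, "excited")
  sgn <- if (excited) 1 else -1
  m_d <- p$mass_delta / acc   # effective masses, eV fs^2 / Angstrom^2
  m_q <- p$mass_q / acc

  rk_d <- 0; rt_d <- 0; rk_q <- 0; rt_q <- 0
  if (!is.null(restraints)) {
    for (r in restraints) {
      if (is.null(r$coordinate) || !r$coordinate %in% c("delta", "q"))
        stop("restraint on unknown coordinate: ",
             if (is.null(r$coordinate)) "<missing>" else r$coordinate)
      k <- if (is.null(r$k)) 10 else r$k
      if (r$coordinate == "delta") { rk_d <- rk_d + k; rt_d <- r$target }
      else { rk_q <- rk_q + k; rt_q <- r$target }
    }
  }

  force_at <- function(d, q) {
    dV1d <- 4 * a4 * d^3 - 2 * b2 * d; dV1q <- kq1 * q
    dV2d <- k2 * d;                    dV2q <- -g + st * q
    V1 <- a4 * d^4 - b2 * d^2 + 0.5 * kq1 * q^2
    V2 <- gap0 + 0.5 * k2 * d^2 - g * q + 0.5 * st * q^2
    D <- V1 - V2
    rt <- sqrt(D * D + c4)
    fd <- -(0.5 * (dV1d + dV2d) + sgn * 0.5 * D * (dV1d - dV2d) / rt)
    fq <- -(0.5 * (dV1q + dV2q) + sgn * 0.5 * D * (dV1q - dV2q) / rt)
    if (rk_d > 0) fd <- fd - rk_d * (d - rt_d)
    if (rk_q > 0) fq <- fq - rk_q * (q - rt_q)
    c(fd, fq, D, rt, V1, V2)
  }

  n_rec <- n_steps + 1L
  T_ <- numeric(n_rec); Dm <- numeric(n_rec); Qm <- numeric(n_rec)
  Vd <- numeric(n_rec); Vq <- numeric(n_rec)
  E0v <- numeric(n_rec); E1v <- numeric(n_rec)
  Sg <- numeric(n_rec); Fo <- numeric(n_rec)

  d <- x0[1]; q <- x0[2]; vd <- v0[1]; vq <- v0[2]
  f <- force_at(d, q)
  kT <- kb * temperature
  c1 <- if (thermostat) exp(-dt / tau) else 1

  record <- function(i, d, q, vd, vq, f) {
    T_[i] <<- (i - 1L) * dt; Dm[i] <<- d; Qm[i] <<- q
    Vd[i] <<- vd; Vq[i] <<- vq
    D <- f[3]; rt <- f[4]; h <- 0.5 * (f[5] + f[6])
    E0v[i] <<- h - 0.5 * rt; E1v[i] <<- h + 0.5 * rt
    # analytic NAC: sigma = -c * dD/dt / (D^2 + 4c^2)
    dDd <- (4 * a4 * d^3 - 2 * b2 * d) - k2 * d
    dDq <- kq1 * q - (-g + st * q)
    Sg[i] <<- -cc * (dDd * vd + dDq * vq) / (D * D + c4)
    Fo[i] <<- p$osc_ref * rt / gap0
  }
  record(1L, d, q, vd, vq, f)

  for (i in seq_len(n_steps)) {
    vd <- vd + 0.5 * dt * f[1] / m_d
    vq <- vq + 0.5 * dt * f[2] / m_q
    d <- d + dt * vd
    q <- q + dt * vq
    f <- force_at(d, q)
    if (!all(is.finite(f[1:2])))
      stop("non-finite forces at frame ", i)
    vd <- vd + 0.5 * dt * f[1] / m_d
    vq <- vq + 0.5 * dt * f[2] / m_q
    if (thermostat) {
      K <- 0.5 * (m_d * vd * vd + m_q * vq * vq)
      r1 <- stats::rnorm(1); s1 <- stats::rnorm(1)^2
      half_kT_K <- 0.5 * kT / K
      a2 <- c1 + (1 - c1) * half_kT_K * (r1 * r1 + s1) +
        2 * r1 * sqrt(c1 * (1 - c1) * half_kT_K)
      al <- sqrt(max(a2, 0))
      vd <- al * vd; vq <- al * vq
    }
    record(i + 1L, d, q, vd, vq, f)
  }

  list(times = T_, delta = Dm, q = Qm, v_delta = Vd, v_q = Vq,
       E_S0 = E0v, E_S1 = E1v, sigma = Sg, osc_strength = Fo)
}

new_trajectory <- function(core, dt, surface = NULL, active_state, seed = NA_integer_,
                           temperature = NA_real_, restraints = NULL) {
  structure(c(core, list(dt = dt, active_state = active_state, seed = seed,
                         temperature = temperature, restraints = restraints,
                         hb_length = if (is.null(surface)) NA_real_ else surface$hb_length,
                         surface = surface)),
            class = "shb_trajectory")
}

#' @export
print.shb_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames, dt = %.3g fs, state = %s\n",
              length(x$times), x$dt, x$active_state))
  if (!is.na(x$hb_length))
    cat(sprintf("  hb_length = %.2f Angstrom, mean gap = %.3f eV\n",
                x$hb_length, mean(x$E_S1 - x$E_S0)))
  invisible(x)
}

# Maxwell-Boltzmann velocities for the two modes.
mb_velocities <- function(params, temperature) {
  kT <- .kc$kb_ev_k * temperature
  acc <- .kc$acc_ev_ang_amu
  c(stats::rnorm(1, 0, sqrt(kT * acc / params$mass_delta)),
    stats::rnorm(1, 0, sqrt(kT * acc / params$mass_q)))
}

#' Sample a thermostatted ground-state trajectory
#'
#' Propagates the two nuclear coordinates on the ground adiabat with velocity
#' Verlet and a stochastic velocity-rescaling thermostat (canonical sampling),
#' recording electronic frames (adiabatic energies, analytic nonadiabatic
#' coupling, surrogate oscillator strength) at every step.
#'
#' @param surface an `shb_surface` from [build_surface()].
#' @param temperature target temperature, K.
#' @param dt time step, fs.
#' @param n_steps number of propagation steps (the record has
#'   `n_steps + 1` frames including the initial one).
#' @param seed integer RNG seed; `NULL` leaves the RNG state untouched.
#' @param tau thermostat relaxation time, fs.
#' @param thermostat logical; disable for microcanonical propagation.
#' @param init optional list with elements `delta`, `q`, `v_delta`, `v_q`
#'   overriding the default start (proton in one well, thermal velocities).
#' @return An `shb_trajectory`.
#' @export
sample_ground_trajectory <- function(surface, temperature = 300, dt = 0.5,
                                     n_steps = 6000L, seed = NULL, tau = 20,
                                     thermostat = TRUE, init = NULL) {
  if (temperature <= 0) stop("temperature must be positive")
  if (dt <= 0) stop("dt must be positive")
  if (!is.null(seed)) set.seed(seed)
  p <- surface$params
  if (is.null(init)) {
    x0 <- c(p$delta_well, 0)
    v0 <- mb_velocities(p, temperature)
  } else {
    x0 <- c(init$delta, init$q)
    v0 <- c(init$v_delta, init$v_q)
  }
  core <- md_core(surface, x0, v0, n_steps, dt, temperature, tau,
                  thermostat, "ground")
  new_trajectory(core, dt, surface, "S0",
                 seed = if (is.null(seed)) NA_integer_ else seed,
                 temperature = temperature)
}

#' Propagate an excited-state (S1) trajectory after vertical excitation
#'
#' The nuclei evolve on the S1 adiabat for the full duration: following the
#' reference protocol no surface switches are performed, so the per-step decay
#' probability remains defined at all times. Restraints are applied as
#' harmonic penalties.
#'
#' @param surface an `shb_surface`.
#' @param init initial frame (list with `delta`, `q`, `v_delta`, `v_q`),
#'   normally the final frame of an equilibrated ground trajectory; see
#'   [trajectory_frame()].
#' @param duration propagation length, fs.
#' @param dt time step, fs; `duration / dt` must be integral.
#' @param restraints optional list of harmonic restraints, each a list with
#'   `coordinate` ("delta" or "q"), `target` and force constant `k`
#'   (eV/Angstrom^2, default 10).
#' @param seed integer RNG seed.
#' @param temperature thermostat target, K.
#' @param tau thermostat relaxation time, fs.
#' @param thermostat logical.
#' @return An `shb_trajectory` with `active_state = "S1"`.
#' @export
run_excited_trajectory <- function(surface, init, duration = 1000, dt = 0.5,
                                   restraints = NULL, seed = NULL,
                                   temperature = 300, tau = 100,
                                   thermostat = TRUE) {
  if (dt <= 0) stop("dt must be positive")
  n_steps <- duration / dt
  if (abs(n_steps - round(n_steps)) > 1e-9)
    stop("duration must be an integral multiple of dt")
  n_steps <- as.integer(round(n_steps))
  if (!is.null(seed)) set.seed(seed)
  core <- md_core(surface, c(init$delta, init$q), c(init$v_delta, init$v_q),
                  n_steps, dt, temperature, tau, thermostat, "excited",
                  restraints)
  new_trajectory(core, dt, surface, "S1",
                 seed = if (is.null(seed)) NA_integer_ else seed,
                 temperature = temperature, restraints = restraints)
}

#' Extract one frame of a trajectory
#'
#' @param traj an `shb_trajectory`.
#' @param i frame index (1-based); defaults to the last frame.
#' @return list with `delta`, `q`, `v_delta`, `v_q`, `time`.
#' @export
trajectory_frame <- function(traj, i = length(traj$times)) {
  if (i < 1 || i > length(traj$times)) stop("frame index out of range")
  list(delta = traj$delta[i], q = traj$q[i],
       v_delta = traj$v_delta[i], v_q = traj$v_q[i], time = traj$times[i])
}

#' Analytic nonadiabatic coupling at a frame
#'
#' Evaluates \eqn{\sigma_{S_0,S_1} = \langle \phi_0 | \nabla_R \phi_1\rangle
#' \cdot dR/dt} in closed form for the two-state model. With a constant
#' diabatic coupling c the adiabatic mixing angle is
#' \eqn{\theta = \tfrac12\,\mathrm{atan2}(2c,\; V_1 - V_2)} and
#' \eqn{\sigma = d\theta/dt = -c\,(\nabla(V_1-V_2)\cdot v)/((V_1-V_2)^2+4c^2)}.
#' The coupling is linear in the velocities and antisymmetric under state
#' exchange.
#'
#' @param surface an `shb_surface`.
#' @param frame list with `delta`, `q`, `v_delta`, `v_q` (see
#'   [trajectory_frame()]).
#' @return scalar coupling, 1/fs.
#' @export
analytic_nac <- function(surface, frame) {
  if (!all(c("delta", "q", "v_delta", "v_q") %in% names(frame)))
    stop("frame must carry delta, q, v_delta, v_q")
  gr <- surface_gradients(surface, frame$delta, frame$q)
  -surface$coupling * (gr$dD[1] * frame$v_delta + gr$dD[2] * frame$v_q) /
    (gr$D^2 + 4 * surface$coupling^2)
}

#' Assemble a trajectory record from electronic time series
#'
#' Builds a minimal `shb_trajectory` directly from externally supplied state
#' energies and couplings (e.g. a linear-sweep avoided-crossing model), for
#' use with [propagate_amplitudes()] and the decay machinery.
#'
#' @param times strictly increasing, uniformly spaced times, fs.
#' @param E_S0,E_S1 state energies per frame, eV (`E_S1 >= E_S0`).
#' @param sigma nonadiabatic coupling per frame, 1/fs.
#' @param osc_strength optional oscillator strengths.
#' @return An `shb_trajectory` (without nuclear coordinates).
#' @export
electronic_trajectory <- function(times, E_S0, E_S1, sigma, osc_strength = NULL) {
  n <- length(times)
  if (n < 2) stop("need at least two frames")
  dts <- diff(times)
  if (any(dts <= 0) || max(abs(dts - dts[1])) > 1e-9 * dts[1])
    stop("times must be strictly increasing with constant spacing")
  if (length(E_S0) != n || length(E_S1) != n || length(sigma) != n)
    stop("E_S0, E_S1 and sigma must have one value per frame")
  if (any(E_S1 < E_S0)) stop("E_S1 must be >= E_S0 in every frame")
  structure(list(times = times, E_S0 = E_S0, E_S1 = E_S1, sigma = sigma,
                 osc_strength = osc_strength, dt = dts[1],
                 active_state = "S1", hb_length = NA_real_),
            class = "shb_trajectory")
}

#' Kinetic energy per frame of a trajectory
#'
#' @param traj an `shb_trajectory` carrying velocities.
#' @return numeric vector, eV.
#' @export
kinetic_energy <- function(traj) {
  p <- traj$surface$params
  acc <- .kc$acc_ev_ang_amu
  0.5 * (p$mass_delta * traj$v_delta^2 + p$mass_q * traj$v_q^2) / acc
}
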