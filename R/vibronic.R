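# Franck-Condon factors for displaced (optionally frequency-changed) harmonic
# oscillators: the vibrational-overlap weights that decide whether an
# electronic transition is 0-0 dominated.

#' Define a harmonic vibronic mode
#'
#' A single effective mode connecting the vibrational ladders of two
#' electronic states. The displacement is the dimensionless mass-weighted
#' shift between the two minima expressed in the ground-state oscillator
#' length; for equal frequencies the Huang-Rhys factor is
#' \eqn{S = d^2/2} and \eqn{FC(0\to0) = e^{-S}}.
#'
#' @param freq_ground vibrational frequency of the (electronic) ground state.
#' @param freq_excited frequency of the excited state (default equal).
#' @param displacement dimensionless displacement d.
#' @param units `"ev"` or `"cm-1"` (only the ratio of the two frequencies
#'   enters the overlap, but the tag keeps inputs honest).
#' @return object of class `harmonic_mode` with fields `freq_ground`,
#'   `freq_excited`, `displacement`, `huang_rhys`, `units`.
#' @export
harmonic_mode <- function(freq_ground, freq_excited = freq_ground,
                          displacement = 0, units = c("ev", "cm-1")) {
  units <- match.arg(units)
  if (freq_ground <= 0 || freq_excited <= 0)
    stop("frequencies must be positive")
  structure(list(freq_ground = freq_ground, freq_excited = freq_excited,
                 displacement = displacement,
                 huang_rhys = displacement^2 / 2, units = units),
            class = "harmonic_mode")
}

#' Mode with a prescribed Huang-Rhys factor
#'
#' Convenience constructor for the equal-frequency case:
#' `displacement = sqrt(2 S)`.
#'
#' @param S Huang-Rhys factor (>= 0).
#' @param freq frequency of both states (default 1, arbitrary units).
#' @inheritParams harmonic_mode
#' @return a `harmonic_mode`.
#' @export
mode_from_huang_rhys <- function(S, freq = 1, units = "ev") {
  if (S < 0) stop("Huang-Rhys factor must be nonnegative")
  harmonic_mode(freq, freq, sqrt(2 * S), units = units)
}

# Normalized dimensionless harmonic-oscillator wavefunction psi_v(x) via the
# stable Hermite-function recurrence.
ho_wavefunction <- function(v, x) {
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

# Overlap <v_excited | v_ground> by dense trapezoid quadrature in the
# ground-state dimensionless coordinate.
fc_overlap_quadrature <- function(mode, v_excited, v_ground, n_grid = 8192L) {
  wr <- mode$freq_excited / mode$freq_ground
  d <- mode$displacement
  half <- 10 + abs(d) + 2 * sqrt(max(v_excited, v_ground) + 1) * max(1, 1 / sqrt(wr))
  x <- seq(-half, half + abs(d), length.out = n_grid)
  h <- x[2] - x[1]
  pg <- ho_wavefunction(v_ground, x)
  pe <- wr^(0.25) * ho_wavefunction(v_excited, sqrt(wr) * (x - d))
  s <- sum(pg * pe) * h
  s
}

#' Franck-Condon factor between two vibrational levels
#'
#' Squared overlap \eqn{|\langle v'|v''\rangle|^2} between level `v_excited`
#' of the excited-state oscillator and `v_ground` of the ground-state
#' oscillator. Equal-frequency 0-to-n factors use the closed Poisson form
#' \eqn{e^{-S} S^n / n!}; the frequency-changed 0-0 factor uses the closed
#' two-Gaussian overlap
#' \eqn{[2\sqrt{\omega'\omega''}/(\omega'+\omega'')]\exp(-\omega'\omega''
#' d^2/(\omega'+\omega''))} (d in ground-state dimensionless units); all other
#' cases are evaluated by dense quadrature of the Hermite-function overlap.
#'
#' @param mode a `harmonic_mode`.
#' @param v_excited,v_ground vibrational quantum numbers (>= 0).
#' @return probability in \[0, 1\].
#' @examples
#' fc_factor(mode_from_huang_rhys(0.198), 0, 0)  # about 0.82
#' @export
fc_factor <- function(mode, v_excited = 0L, v_ground = 0L) {
  if (!inherits(mode, "harmonic_mode")) stop("mode must be a harmonic_mode")
  if (v_excited < 0 || v_ground < 0) stop("quantum numbers must be >= 0")
  equal <- abs(mode$freq_excited - mode$freq_ground) <
    1e-12 * mode$freq_ground
  S <- mode$huang_rhys
  if (equal && (v_excited == 0L || v_ground == 0L)) {
    n <- max(v_excited, v_ground)
    return(exp(-S) * S^n / factorial(n))
  }
  if (v_excited == 0L && v_ground == 0L) {
    wg <- mode$freq_ground; we <- mode$freq_excited
    wr <- we / wg
    d <- mode$displacement
    return(2 * sqrt(wr) / (1 + wr) * exp(-wr * d^2 / (1 + wr)))
  }
  fc_overlap_quadrature(mode, v_excited, v_ground)^2
}

#' Table of Franck-Condon factors from the lowest excited vibrational level
#'
#' @param mode a `harmonic_mode`.
#' @param n_max highest ground-state quantum number (default 10).
#' @return data.frame with columns `v_ground` and `fc`.
#' @export
fc_table <- function(mode, n_max = 10L) {
  data.frame(v_ground = 0:n_max,
             fc = vapply(0:n_max, function(n) fc_factor(mode, 0L, n),
                         numeric(1)))
}

#' Infer the Huang-Rhys factor from a 0-0 Franck-Condon factor
#'
#' Inverse of the equal-frequency relation \eqn{FC(0\to0) = e^{-S}}:
#' \eqn{S = -\ln FC_{00}}.
#'
#' @param fc_00 0-0 factor in (0, 1\].
#' @return Huang-Rhys factor S.
#' @examples
#' infer_huang_rhys(0.82)  # about 0.198
#' @export
infer_huang_rhys <- function(fc_00) {
  if (any(fc_00 <= 0) || any(fc_00 > 1))
    stop("fc_00 must lie in (0, 1]")
  -log(fc_00)
}

#' Is the emission 0-0 dominated?
#'
#' The transition is classified as 0-0 dominant when \eqn{FC(0\to0)} exceeds
#' the threshold and every \eqn{FC(0\to n)} up to `n_max`.
#'
#' @param mode a `harmonic_mode`.
#' @param threshold dominance threshold in (0, 1), default 0.5.
#' @param n_max highest competing level considered (default 10).
#' @return `TRUE` (dominant) or `FALSE` (not dominant).
#' @export
classify_00_dominance <- function(mode, threshold = 0.5, n_max = 10L) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly inside (0, 1)")
  tab <- fc_table(mode, n_max)
  fc00 <- tab$fc[1]
  fc00 > threshold && fc00 >= max(tab$fc)
}
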