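#' Default parameter set for the two-state model surface
#'
#' The surrogate electronic structure is a two-diabat Hamiltonian over two
#' nuclear degrees of freedom: the proton-transfer coordinate \eqn{\delta}
#' (difference of the two O--H distances across the hydrogen bond, Angstrom)
#' and a collective distortion coordinate \eqn{q} (carbonyl stretch plus ring
#' deplanarization, Angstrom, unit effective mass).
#'
#' The ground diabat is a symmetric quartic double well in \eqn{\delta} plus a
#' harmonic term in \eqn{q}; the excited diabat is a displaced harmonic in
#' \eqn{\delta} plus a linear gap-closing term in \eqn{q} opposed by a
#' stiffening quadratic whose force constant decays with the donor--acceptor
#' distance. A short hydrogen bond therefore gives (i) a proton-transfer
#' barrier at or below thermal energy and (ii) a stiff distortion mode that
#' keeps the S1--S0 gap open; stretching the hydrogen bond raises the barrier
#' and softens the distortion mode so that the gap can close.
#'
#' @param ... named overrides of any default listed below.
#' @return Named list of surface parameters:
#' \describe{
#'   \item{delta_well}{position of the diabatic double-well minima, Angstrom (0.35)}
#'   \item{barrier_ref}{ground-state proton-transfer barrier at a 2.5 Angstrom
#'     hydrogen bond, eV (0.022, i.e. just below kT at 300 K)}
#'   \item{barrier_slope}{barrier increase per Angstrom of hydrogen-bond
#'     lengthening, eV/Angstrom (0.55)}
#'   \item{k_q_ground}{ground-diabat force constant of q, eV/Angstrom^2 (2.0)}
#'   \item{k_delta_excited}{excited-diabat force constant of delta, eV/Angstrom^2 (1.5)}
#'   \item{gap0}{vertical diabatic separation at the origin, eV (3.25)}
#'   \item{gap_coupling}{linear gap-closing coefficient along q, eV/Angstrom (1.5)}
#'   \item{stiff_ref}{excited-diabat q stiffening at 2.5 Angstrom, eV/Angstrom^2 (6.0)}
#'   \item{stiff_decay}{exponential decay rate of the stiffening with
#'     hydrogen-bond length, 1/Angstrom (1.2)}
#'   \item{coupling}{constant diabatic coupling c, eV (0.12); the adiabatic
#'     gap can never fall below 2c}
#'   \item{mass_delta, mass_q}{effective masses, amu (1, 1)}
#'   \item{gap_target}{nominal emission gap the short-bond surface is tuned
#'     to, eV (3.0)}
#'   \item{osc_ref}{oscillator-strength scale of the surrogate transition (0.1)}
#' }
#' @export
surface_params <- function(...) {
  p <- list(
    delta_well      = 0.35,
    barrier_ref     = 0.022,
    barrier_slope   = 0.55,
    k_q_ground      = 2.0,
    k_delta_excited = 1.5,
    gap0            = 3.25,
    gap_coupling    = 1.5,
    stiff_ref       = 6.0,
    stiff_decay     = 1.2,
    coupling        = 0.12,
    mass_delta      = 1.0,
    mass_q          = 1.0,
    gap_target      = 3.0,
    osc_ref         = 0.1
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown surface parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  p
}

#' Build a two-state model surface for a given hydrogen-bond length
#'
#' @param hb_length donor--acceptor distance, Angstrom; supported range
#'   \[2.4, 5.0\].
#' @param params parameter list from [surface_params()].
#' @return An object of class `shb_surface`.
#' @examples
#' s <- build_surface(2.5)
#' surface_barrier(s)   # proton-transfer barrier, eV
#' @export
build_surface <- function(hb_length, params = surface_params()) {
  if (!is.numeric(hb_length) || length(hb_length) != 1L || !is.finite(hb_length))
    stop("hb_length must be a single finite number")
  if (hb_length < 2.4 || hb_length > 5.0)
    stop("hb_length ", hb_length, " outside supported range [2.4, 5.0] Angstrom")
  if (params$coupling <= 0)
    stop("diabatic coupling must be positive (a true surface crossing is not supported)")
  barrier <- params$barrier_ref + params$barrier_slope * (hb_length - 2.5)
  dm <- params$delta_well
  b <- 2 * barrier / dm^2        # quartic double well a d^4 - b d^2
  a <- b / (2 * dm^2)            # minima at +/- dm, depth -barrier
  structure(list(
    hb_length  = hb_length,
    coupling   = params$coupling,
    stiffening = params$stiff_ref * exp(-params$stiff_decay * (hb_length - 2.5)),
    quartic_a  = a,
    quartic_b  = b,
    coordinate_labels = c("delta", "q"),
    params     = params
  ), class = "shb_surface")
}

#' @export
print.shb_surface <- function(x, ...) {
  cat("Two-state model surface\n")
  cat(sprintf("  hydrogen-bond length: %.2f Angstrom\n", x$hb_length))
  cat(sprintf("  diabatic coupling:    %.3f eV (minimum gap %.3f eV)\n",
              x$coupling, 2 * x$coupling))
  cat(sprintf("  delta barrier:        %.4f eV\n", surface_barrier(x)))
  cat(sprintf("  q stiffening:         %.3f eV/Angstrom^2\n", x$stiffening))
  invisible(x)
}

#' Diabatic potentials of a model surface
#'
#' Vectorized over `delta` and `q`.
#'
#' @param surface an `shb_surface`.
#' @param delta proton-transfer coordinate(s), Angstrom.
#' @param q distortion coordinate(s), Angstrom.
#' @return list with numeric vectors `V1` (ground diabat) and `V2`
#'   (excited diabat), eV.
#' @export
diabats <- function(surface, delta, q) {
  p <- surface$params
  V1 <- surface$quartic_a * delta^4 - surface$quartic_b * delta^2 +
    0.5 * p$k_q_ground * q^2
  V2 <- p$gap0 + 0.5 * p$k_delta_excited * delta^2 - p$gap_coupling * q +
    0.5 * surface$stiffening * q^2
  list(V1 = V1, V2 = V2)
}

#' Adiabatic energies of a model surface
#'
#' Diagonalizes the 2x2 diabatic Hamiltonian with constant coupling c:
#' \eqn{E_\pm = (V_1+V_2)/2 \pm \sqrt{(V_1-V_2)^2 + 4c^2}/2}. The gap is
#' bounded below by 2c everywhere, so the surfaces never truly cross.
#'
#' @inheritParams diabats
#' @return list with vectors `E0`, `E1` (eV) and `gap` = `E1 - E0`.
#' @export
adiabatic_energies <- function(surface, delta, q) {
  v <- diabats(surface, delta, q)
  D <- v$V1 - v$V2
  rt <- sqrt(D^2 + 4 * surface$coupling^2)
  h <- 0.5 * (v$V1 + v$V2)
  list(E0 = h - 0.5 * rt, E1 = h + 0.5 * rt, gap = rt)
}

# Analytic gradients of diabats and adiabats at a single point.
# Returns list(dV1, dV2, dD, dE0, dE1) each length-2 (delta, q), plus D, rt.
surface_gradients <- function(surface, delta, q) {
  p <- surface$params
  dV1 <- c(4 * surface$quartic_a * delta^3 - 2 * surface$quartic_b * delta,
           p$k_q_ground * q)
  dV2 <- c(p$k_delta_excited * delta,
           -p$gap_coupling + surface$stiffening * q)
  v <- diabats(surface, delta, q)
  D <- v$V1 - v$V2
  rt <- sqrt(D^2 + 4 * surface$coupling^2)
  dD <- dV1 - dV2
  half <- 0.5 * (dV1 + dV2)
  corr <- 0.5 * D * dD / rt
  list(dV1 = dV1, dV2 = dV2, dD = dD, D = D, rt = rt,
       dE0 = half - corr, dE1 = half + corr)
}

#' Ground-state proton-transfer barrier of a model surface
#'
#' Scans the ground adiabat along \eqn{\delta} at \eqn{q = 0} on a dense grid
#' and returns the height of the maximum between the two wells relative to the
#' global minimum.
#'
#' @param surface an `shb_surface`.
#' @param n_grid number of grid points.
#' @return barrier height, eV.
#' @export
surface_barrier <- function(surface, n_grid = 2001L) {
  dm <- surface$params$delta_well
  dd <- seq(-1.5 * dm, 1.5 * dm, length.out = n_grid)
  e <- adiabatic_energies(surface, dd, 0)$E0
  imin <- which.min(e)
  # maximum between the two minima: restrict to the interval between the two
  # symmetric wells
  inner <- dd > -dm & dd < dm
  max(e[inner]) - e[imin]
}

#' Minimum adiabatic gap along the distortion coordinate
#'
#' @param surface an `shb_surface`.
#' @param delta fixed proton-transfer coordinate, Angstrom.
#' @param q_range range of q to scan, Angstrom.
#' @param n_grid grid size.
#' @return minimum of `E1 - E0` over the scan, eV (never below `2 * coupling`).
#' @export
surface_min_gap <- function(surface, delta = 0, q_range = c(-1, 4), n_grid = 4001L) {
  q <- seq(q_range[1], q_range[2], length.out = n_grid)
  min(adiabatic_energies(surface, delta, q)$gap)
}
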