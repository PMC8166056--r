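# Cartesian geometries: a light container plus the toy molecule used to give
# the two model coordinates a concrete molecular embedding (five-membered ring
# with a carbonyl, bridged by an O1-H-O2 hydrogen bond).

#' Construct a Cartesian geometry
#'
#' @param elements character vector of element symbols.
#' @param coords numeric matrix, one row per atom, columns x, y, z (Angstrom).
#' @param metadata optional named list (e.g. time, energies) carried along.
#' @return object of class `shb_geometry`.
#' @export
geometry <- function(elements, coords, metadata = list()) {
  coords <- as.matrix(coords)
  if (nrow(coords) != length(elements) || ncol(coords) != 3)
    stop("coords must be an n x 3 matrix matching elements")
  structure(list(elements = as.character(elements), coords = coords,
                 metadata = metadata),
            class = "shb_geometry")
}

#' @export
print.shb_geometry <- function(x, ...) {
  cat(sprintf("Geometry: %d atoms (%s)\n", length(x$elements),
              paste(unique(x$elements), collapse = ", ")))
  invisible(x)
}

#' Interatomic distance
#'
#' @param geom an `shb_geometry`.
#' @param i,j atom indices.
#' @return distance in Angstrom.
#' @export
atom_distance <- function(geom, i, j) {
  n <- nrow(geom$coords)
  if (any(c(i, j) < 1) || any(c(i, j) > n)) stop("atom index out of range")
  sqrt(sum((geom$coords[i, ] - geom$coords[j, ])^2))
}

#' Toy molecular embedding of the model coordinates
#'
#' Builds Cartesian coordinates of a five-membered ring (four carbons and a
#' nitrogen), a carbonyl oxygen, and an O1-H-O2 hydrogen-bond bridge. The
#' proton-transfer coordinate `delta` places the shared proton between the two
#' bridge oxygens (`d(O1,H) - d(O2,H) = delta`), and the distortion coordinate
#' `q` simultaneously stretches the C=O bond (`1.23 + 0.075 q` Angstrom) and
#' lifts one ring atom out of plane (`0.5 q` Angstrom), mimicking the carbonyl
#' stretch and ring deplanarization that accompany gap closure.
#'
#' @param delta proton-transfer coordinate, Angstrom.
#' @param q distortion coordinate, Angstrom.
#' @param hb_length O1--O2 distance, Angstrom.
#' @return An `shb_geometry` with attribute `atoms`, a named list of indices
#'   (`ring`, `carbonyl_c`, `carbonyl_o`, `o1`, `h`, `o2`).
#' @export
toy_geometry <- function(delta = 0, q = 0, hb_length = 2.5) {
  if (abs(delta) >= hb_length)
    stop("|delta| must be smaller than hb_length")
  r0 <- 1.2
  ang <- 2 * pi * (0:4) / 5
  ring <- cbind(r0 * cos(ang), r0 * sin(ang), 0)
  ring[4, 3] <- ring[4, 3] + 0.5 * q               # envelope pucker
  co_len <- 1.23 + 0.075 * q
  # carbonyl on ring atom 2, pointing radially outward (away from the ring
  # nitrogen so the O...N contact stays beyond hydrogen-bonding range)
  carbonyl_o <- c((r0 + co_len) * cos(ang[2]), (r0 + co_len) * sin(ang[2]), 0)
  cx <- 6.0
  o1 <- c(cx, -hb_length / 2, 0)
  o2 <- c(cx, hb_length / 2, 0)
  h <- c(cx, -hb_length / 2 + (hb_length + delta) / 2, 0)
  g <- geometry(c("C", "C", "C", "C", "N", "O", "O", "H", "O"),
                rbind(ring, carbonyl_o, o1, h, o2))
  attr(g, "atoms") <- list(ring = 1:5, carbonyl_c = 2L, carbonyl_o = 6L,
                           o1 = 7L, h = 8L, o2 = 9L)
  g
}

#' Cartesian frames of a model trajectory
#'
#' Maps the (`delta`, `q`) record of a trajectory onto [toy_geometry()]
#' frames, attaching the per-frame electronic metadata.
#'
#' @param traj an `shb_trajectory` with nuclear coordinates.
#' @param every keep every `every`-th frame (default 1).
#' @return list of `shb_geometry` frames.
#' @export
trajectory_frames <- function(traj, every = 1L) {
  if (is.null(traj$delta)) stop("trajectory carries no nuclear coordinates")
  hb <- if (is.na(traj$hb_length)) 2.5 else traj$hb_length
  idx <- seq(1L, length(traj$times), by = every)
  lapply(idx, function(i) {
    g <- toy_geometry(traj$delta[i], traj$q[i], hb)
    g$metadata <- list(time = traj$times[i], E_S0 = traj$E_S0[i],
                       E_S1 = traj$E_S1[i], sigma = traj$sigma[i],
                       f = traj$osc_strength[i])
    g
  })
}
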