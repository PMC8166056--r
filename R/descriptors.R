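# Geometric and thermodynamic descriptors: proton-transfer coordinate,
# free-energy profiles with well classification, dihedral-based ring
# deplanarization, bond-length histograms and hydrogen-bond enumeration.

#' Proton-transfer coordinate of a geometry
#'
#' Returns \eqn{d(O_1,H) - d(O_2,H)}, the antisymmetric distance difference
#' locating the shared proton between the two bridge oxygens. Negative values
#' mean the proton sits closer to O1; the coordinate changes sign under
#' exchange of the two oxygens.
#'
#' @param geom an `shb_geometry`.
#' @param o1,h,o2 atom indices (distinct).
#' @return coordinate in Angstrom.
#' @export
proton_transfer_coordinate <- function(geom, o1, h, o2) {
  idx <- c(o1, h, o2)
  if (anyDuplicated(idx)) stop("o1, h and o2 must be distinct atoms")
  if (any(idx < 1) || any(idx > nrow(geom$coords)))
    stop("atom index out of range")
  atom_distance(geom, o1, h) - atom_distance(geom, o2, h)
}

#' Free-energy profile from sampled coordinate values
#'
#' Estimates \eqn{F(\delta) = -k_B T \ln \hat\rho(\delta)} from a normalized
#' histogram of the samples, shifted so that the minimum is zero. Bins with no
#' samples are reported as `NA` (their free energy is undefined), never zero.
#'
#' @param samples numeric vector of coordinate samples (>= 1000).
#' @param temperature K.
#' @param n_bins number of bins (default 50) over the sampled range padded by
#'   5 percent on each side.
#' @param units `"kT"` (default) or `"eV"`.
#' @return object of class `fe_profile` with `bin_centers`, `free_energy`,
#'   `n_samples` (per bin), `temperature`, `units`.
#' @export
free_energy_profile <- function(samples, temperature = 300, n_bins = 50L,
                                units = c("kT", "eV")) {
  units <- match.arg(units)
  samples <- samples[is.finite(samples)]
  if (length(samples) < 1000)
    stop("need at least 1000 samples for a free-energy profile")
  if (temperature <= 0) stop("temperature must be positive")
  rg <- range(samples)
  pad <- 0.05 * diff(rg)
  if (pad == 0) pad <- 1e-6
  breaks <- seq(rg[1] - pad, rg[2] + pad, length.out = n_bins + 1L)
  counts <- tabulate(findInterval(samples, breaks, rightmost.closed = TRUE),
                     nbins = n_bins)
  rho <- counts / sum(counts)
  f <- ifelse(counts > 0, -log(rho), NA_real_)
  f <- f - min(f, na.rm = TRUE)
  if (units == "eV") f <- f * .kc$kb_ev_k * temperature
  structure(list(bin_centers = 0.5 * (breaks[-1] + breaks[-(n_bins + 1L)]),
                 free_energy = f, n_samples = counts,
                 temperature = temperature, units = units),
            class = "fe_profile")
}

#' @export
print.fe_profile <- function(x, ...) {
  cl <- classify_wells(x)
  cat(sprintf("Free-energy profile: %d bins (%d sampled), %s well",
              length(x$bin_centers), sum(x$n_samples > 0), cl$wells))
  if (cl$wells == "double")
    cat(sprintf(", barrier %.3g %s", cl$barrier, x$units))
  cat("\n")
  invisible(x)
}

#' Classify a free-energy profile as single- or double-well
#'
#' A profile is double-well if two thermally populated local minima are
#' separated by a maximum exceeding both by more than the noise threshold.
#' Candidate minima are searched on a lightly smoothed profile (3-bin moving
#' average) and must lie within `well_depth_max` of the global minimum --
#' spurious minima produced by sampling noise in sparsely visited tail bins
#' carry essentially no population and are not wells. Unsampled (`NA`) bins
#' are treated as impassable, so a second well the trajectory never visited
#' does not count.
#'
#' @param profile an `fe_profile` with at least 20 bins.
#' @param noise_threshold minimum significant barrier, in units of kT
#'   (default 0.5).
#' @param well_depth_max maximum free energy (kT above the global minimum)
#'   for a candidate well (default 3, i.e. at least ~5 percent relative
#'   population).
#' @param min_separation minimum number of bins between the two minima
#'   (default 3).
#' @return list with `wells` ("single" or "double"), `barrier` (height of the
#'   separating maximum above the shallower minimum, profile units; `NA` for
#'   single wells), `minima` (bin centers of the classified minima).
#' @export
classify_wells <- function(profile, noise_threshold = 0.5, well_depth_max = 3,
                           min_separation = 3L) {
  f <- profile$free_energy
  if (length(f) < 20) stop("profile must have at least 20 bins")
  if (all(is.na(f))) stop("profile is undefined in every bin")
  kT <- .kc$kb_ev_k * profile$temperature
  scale <- if (profile$units == "eV") kT else 1   # thresholds are stated in kT
  thr <- noise_threshold * scale
  depth_max <- well_depth_max * scale
  fx <- ifelse(is.na(f), Inf, f)
  n <- length(fx)
  # NA-aware 3-bin moving average for minimum detection only
  sm <- vapply(seq_len(n), function(i) {
    w <- fx[max(1, i - 1):min(n, i + 1)]
    w <- w[is.finite(w)]
    if (length(w)) mean(w) else Inf
  }, numeric(1))
  is_min <- vapply(seq_len(n), function(i) {
    if (!is.finite(sm[i]) || !is.finite(fx[i])) return(FALSE)
    left <- if (i > 1) sm[i - 1] else Inf
    right <- if (i < n) sm[i + 1] else Inf
    sm[i] <= left && sm[i] <= right && (sm[i] < left || sm[i] < right) &&
      fx[i] - min(fx[is.finite(fx)]) <= depth_max
  }, logical(1))
  mins <- which(is_min)
  best <- NULL
  if (length(mins) >= 2) {
    for (ii in seq_len(length(mins) - 1)) {
      for (jj in seq(ii + 1, length(mins))) {
        i <- mins[ii]; j <- mins[jj]
        if (j - i < min_separation) next
        sep <- max(fx[(i + 1):(j - 1)])
        if (!is.finite(sep)) next   # unsampled gap between the candidates
        depth <- sep - max(fx[i], fx[j])
        if (depth > thr && (is.null(best) || depth > best$depth))
          best <- list(i = i, j = j, sep = sep, depth = depth)
      }
    }
  }
  if (is.null(best)) {
    list(wells = "single", barrier = NA_real_,
         minima = profile$bin_centers[which.min(fx)])
  } else {
    list(wells = "double", barrier = best$depth,
         minima = profile$bin_centers[c(best$i, best$j)])
  }
}

# Torsion angle (degrees) for four points, with collinearity check.
torsion_angle <- function(p1, p2, p3, p4, atoms = c(1, 2, 3, 4)) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10)
    stop("torsion undefined: atoms ", paste(atoms, collapse = "-"),
         " contain a collinear triple")
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  nb2 <- sqrt(sum(b2^2))
  atan2(sum(m1 * n2) / nb2, sum(n1 * n2)) * 180 / pi
}

#' Ring deplanarization of a five-membered ring
#'
#' Sum over the five intra-ring torsions \eqn{\tau(i, i+1, i+2, i+3)}
#' (indices mod 5) of their magnitudes, in degrees. Zero for a perfectly
#' planar ring; invariant under rigid rotation and translation.
#'
#' @param geom an `shb_geometry`.
#' @param ring_atoms ordered vector of 5 distinct atom indices forming the
#'   cycle.
#' @param signed if `TRUE`, sum the signed torsions instead of magnitudes.
#' @return deplanarization in degrees.
#' @export
ring_deplanarization <- function(geom, ring_atoms, signed = FALSE) {
  if (length(ring_atoms) != 5 || anyDuplicated(ring_atoms))
    stop("ring_atoms must be 5 distinct indices")
  if (any(ring_atoms < 1) || any(ring_atoms > nrow(geom$coords)))
    stop("atom index out of range")
  tot <- 0
  for (k in 0:4) {
    idx <- ring_atoms[(k + 0:3) %% 5 + 1]
    tau <- torsion_angle(geom$coords[idx[1], ], geom$coords[idx[2], ],
                         geom$coords[idx[3], ], geom$coords[idx[4], ],
                         atoms = idx)
    tot <- tot + if (signed) tau else abs(tau)
  }
  tot
}

#' Bond-length time series and histogram along a trajectory
#'
#' Euclidean distance between two atoms of the Cartesian embedding for every
#' frame of a model trajectory, plus a histogram normalized to unit mass.
#'
#' @param traj an `shb_trajectory` with nuclear coordinates (frames are
#'   embedded via [trajectory_frames()]), or a list of `shb_geometry` frames.
#' @param i,j atom indices.
#' @param n_bins histogram bins.
#' @return list with `series` (Angstrom), `mids`, `mass` (sums to 1),
#'   `breaks`, `mode` (bin center of the most massive bin).
#' @export
bond_length_series <- function(traj, i, j, n_bins = 50L) {
  frames <- if (inherits(traj, "shb_trajectory")) trajectory_frames(traj) else traj
  n_atoms <- nrow(frames[[1]]$coords)
  if (any(c(i, j) < 1) || any(c(i, j) > n_atoms)) stop("atom index out of range")
  series <- vapply(frames, function(g)
    sqrt(sum((g$coords[i, ] - g$coords[j, ])^2)), numeric(1))
  rg <- range(series)
  if (diff(rg) == 0) rg <- rg + c(-1e-6, 1e-6)
  breaks <- seq(rg[1], rg[2], length.out = n_bins + 1L)
  counts <- tabulate(findInterval(series, breaks, rightmost.closed = TRUE),
                     nbins = n_bins)
  mass <- counts / sum(counts)
  mids <- 0.5 * (breaks[-1] + breaks[-(n_bins + 1L)])
  list(series = series, mids = mids, mass = mass, breaks = breaks,
       mode = mids[which.max(mass)])
}

#' Enumerate hydrogen-bond donor--acceptor distances in a geometry
#'
#' Lists all pairs of heavy hydrogen-bonding atoms (O/N by default) closer
#' than the cutoff, sorted by distance, and flags short hydrogen bonds.
#'
#' @param geom an `shb_geometry` with element labels.
#' @param elements element symbols considered as donors/acceptors.
#' @param cutoff maximum heavy-atom separation, Angstrom (default 3.2).
#' @param shb_cutoff pairs at or below this distance are flagged as short
#'   hydrogen bonds (default 2.6).
#' @return data.frame with columns `i`, `j`, `element_i`, `element_j`,
#'   `distance`, `shb` (logical), sorted ascending by distance; zero rows if
#'   no pair is within the cutoff.
#' @export
hb_distances <- function(geom, elements = c("O", "N"), cutoff = 3.2,
                         shb_cutoff = 2.6) {
  sel <- which(toupper(geom$elements) %in% toupper(elements))
  if (length(sel) == 0)
    stop("geometry has no atoms of element(s) ", paste(elements, collapse = "/"))
  out <- data.frame(i = integer(), j = integer(),
                    element_i = character(), element_j = character(),
                    distance = numeric(), shb = logical())
  if (length(sel) >= 2) {
    pairs <- utils::combn(sel, 2)
    d <- apply(pairs, 2, function(p)
      sqrt(sum((geom$coords[p[1], ] - geom$coords[p[2], ])^2)))
    keep <- d <= cutoff
    if (any(keep)) {
      out <- data.frame(i = pairs[1, keep], j = pairs[2, keep],
                        element_i = geom$elements[pairs[1, keep]],
                        element_j = geom$elements[pairs[2, keep]],
                        distance = d[keep], shb = d[keep] <= shb_cutoff)
      out <- out[order(out$distance), , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  out
}
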