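# Absorption-spectrum machinery: stick broadening, thermal averaging over
# sampled frames, second-derivative peak localization, and the energy /
# wavelength unit conversions used when reporting results.

#' Broaden excitation sticks into a spectrum
#'
#' Sums one lineshape per stick, weighted by oscillator strength, on an energy
#' grid. The default lineshape is a Lorentzian with HWHM equal to the
#' intrinsic bandwidth (0.003 Ry, about 0.0408 eV), normalized so that the
#' integral of a single broadened stick over an unbounded grid equals its
#' oscillator strength.
#'
#' @param energies stick excitation energies, eV (positive).
#' @param strengths oscillator strengths (same length).
#' @param bandwidth broadening parameter, eV: Lorentzian HWHM or Gaussian
#'   standard deviation.
#' @param grid energy axis, eV; default spans the sticks plus 80 bandwidths on
#'   each side at a spacing of `bandwidth / 10` (the wide span keeps the
#'   slowly decaying Lorentzian tails inside the grid, so a single stick
#'   integrates to its oscillator strength within 1 percent).
#' @param lineshape `"lorentzian"` (default) or `"gaussian"`.
#' @return object of class `spectrum_model` with `grid`, `intensity`,
#'   `sticks` (data.frame), `bandwidth`, `lineshape`.
#' @export
broaden_sticks <- function(energies, strengths, bandwidth = 0.0408,
                           grid = NULL, lineshape = c("lorentzian", "gaussian")) {
  lineshape <- match.arg(lineshape)
  if (bandwidth <= 0) stop("bandwidth must be positive")
  if (length(energies) != length(strengths))
    stop("energies and strengths must have equal length")
  if (length(energies) == 0) {
    warning("no sticks supplied; returning an empty spectrum")
    if (is.null(grid)) grid <- numeric()
    return(structure(list(grid = grid, intensity = rep(0, length(grid)),
                          sticks = data.frame(energy_ev = numeric(),
                                              osc_strength = numeric()),
                          bandwidth = bandwidth, lineshape = lineshape),
                     class = "spectrum_model"))
  }
  if (any(energies <= 0)) stop("stick energies must be positive")
  if (is.null(grid))
    grid <- seq(min(energies) - 80 * bandwidth, max(energies) + 80 * bandwidth,
                by = bandwidth / 10)
  intensity <- rep(0, length(grid))
  for (k in seq_along(energies)) {
    de <- grid - energies[k]
    intensity <- intensity + if (lineshape == "lorentzian")
      strengths[k] * (bandwidth / pi) / (de^2 + bandwidth^2)
    else
      strengths[k] * stats::dnorm(de, sd = bandwidth)
  }
  structure(list(grid = grid, intensity = intensity,
                 sticks = data.frame(energy_ev = energies,
                                     osc_strength = strengths),
                 bandwidth = bandwidth, lineshape = lineshape),
            class = "spectrum_model")
}

#' @export
print.spectrum_model <- function(x, ...) {
  cat(sprintf("Spectrum: %d sticks, %d grid points, bandwidth %.4g eV (%s)\n",
              nrow(x$sticks), length(x$grid), x$bandwidth, x$lineshape))
  invisible(x)
}

#' Thermally averaged spectrum over randomly sampled frames
#'
#' Draws a uniform random subsample (without replacement) of the per-frame
#' spectra and returns their pointwise mean, emulating the averaging of
#' spectra over frames sampled from a molecular-dynamics run.
#'
#' @param frame_spectra list of `spectrum_model`s sharing one grid.
#' @param n_sample number of frames to average (default 25).
#' @param seed integer seed for the subsample.
#' @return a `spectrum_model` (mean intensity; sticks pooled from the sampled
#'   frames).
#' @export
thermal_average <- function(frame_spectra, n_sample = 25L, seed = NULL) {
  if (n_sample > length(frame_spectra))
    stop("n_sample exceeds the number of available frames")
  g0 <- frame_spectra[[1]]$grid
  for (s in frame_spectra)
    if (length(s$grid) != length(g0) || max(abs(s$grid - g0)) > 1e-12)
      stop("all frame spectra must share the same grid")
  if (!is.null(seed)) set.seed(seed)
  pick <- sample(length(frame_spectra), n_sample)
  mat <- vapply(frame_spectra[pick], function(s) s$intensity, numeric(length(g0)))
  sticks <- do.call(rbind, lapply(frame_spectra[pick], function(s) s$sticks))
  structure(list(grid = g0, intensity = rowMeans(mat), sticks = sticks,
                 bandwidth = frame_spectra[[1]]$bandwidth,
                 lineshape = frame_spectra[[1]]$lineshape),
            class = "spectrum_model")
}

#' Locate spectral peaks via the smoothed second derivative
#'
#' Smooths the spectrum with a Savitzky-Golay filter and reports local minima
#' of its second derivative (peak positions appear as pronounced negative
#' curvature, which resolves shoulders that a direct maximum search misses).
#'
#' @param spectrum a `spectrum_model` on a uniform grid.
#' @param window Savitzky-Golay window length (odd, default 7).
#' @param poly_order polynomial order (default 3).
#' @param prominence minimum curvature magnitude relative to the strongest
#'   curvature for a minimum to count as a peak (default 0.05).
#' @return data.frame with `energy_ev`, `wavelength_nm`, `curvature`, sorted
#'   by energy; zero rows for a featureless spectrum.
#' @export
second_derivative_peaks <- function(spectrum, window = 7L, poly_order = 3L,
                                    prominence = 0.05) {
  g <- spectrum$grid
  if (length(g) < window)
    stop("grid shorter than the smoothing window")
  hs <- diff(g)
  if (max(abs(hs - hs[1])) > 1e-9 * hs[1]) stop("grid must be uniform")
  d2 <- signal::sgolayfilt(spectrum$intensity, p = poly_order, n = window,
                           m = 2, ts = hs[1])
  n <- length(d2)
  scale <- max(abs(d2))
  # featureless spectra: curvature at or below the rounding noise floor of
  # the finite-difference scale intensity / spacing^2
  noise_floor <- 1e-10 * max(abs(spectrum$intensity), 0) / hs[1]^2
  if (scale <= noise_floor)
    return(data.frame(energy_ev = numeric(), wavelength_nm = numeric(),
                      curvature = numeric()))
  i <- 2:(n - 1)
  loc_min <- i[d2[i] < d2[i - 1] & d2[i] <= d2[i + 1] &
                 d2[i] < -prominence * scale]
  data.frame(energy_ev = g[loc_min],
             wavelength_nm = ev_to_nm(g[loc_min]),
             curvature = d2[loc_min])
}

#' Convert photon energy in eV to wavelength in nm
#'
#' \eqn{\lambda = 1239.84193 / E}.
#'
#' @param e energy, eV (positive).
#' @return wavelength, nm.
#' @examples
#' round(ev_to_nm(3.0))  # 413
#' @export
ev_to_nm <- function(e) {
  if (any(e <= 0)) stop("energy must be positive")
  .kc$hc_ev_nm / e
}

#' Convert wavelength in nm to photon energy in eV
#'
#' @param nm wavelength, nm (positive).
#' @return energy, eV.
#' @export
nm_to_ev <- function(nm) {
  if (any(nm <= 0)) stop("wavelength must be positive")
  .kc$hc_ev_nm / nm
}

#' Convert Rydberg to eV
#'
#' @param ry energy in Rydberg (positive).
#' @return energy in eV (1 Ry = 13.605693 eV).
#' @examples
#' signif(ry_to_ev(0.003), 3)  # 0.0408
#' @export
ry_to_ev <- function(ry) {
  if (any(ry <= 0)) stop("energy must be positive")
  .kc$ry_ev * ry
}
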