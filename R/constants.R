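#' Physical constants used throughout the package
#'
#' Returns the centralized table of unit constants used by every numerical
#' routine in the package. Internal units are eV (energy), Angstrom (length),
#' femtosecond (time), amu (mass) and Kelvin (temperature).
#'
#' @return A named list with elements:
#'   \describe{
#'     \item{hbar_ev_fs}{reduced Planck constant, eV fs}
#'     \item{kb_ev_k}{Boltzmann constant, eV/K}
#'     \item{acc_ev_ang_amu}{acceleration produced by a force of 1 eV/Angstrom
#'       acting on 1 amu, in Angstrom/fs^2}
#'     \item{hc_ev_nm}{h*c, eV nm (energy/wavelength conversion)}
#'     \item{ry_ev}{one Rydberg in eV}
#'   }
#' @examples
#' shb_constants()$kb_ev_k * 300  # thermal energy at 300 K, eV
#' @export
shb_constants <- function() {
  list(
    hbar_ev_fs     = 0.6582119569,
    kb_ev_k        = 8.617333262e-5,
    acc_ev_ang_amu = 9.64853322e-3,
    hc_ev_nm       = 1239.84193,
    ry_ev          = 13.605693
  )
}

.kc <- shb_constants()
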