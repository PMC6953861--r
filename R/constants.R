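#' Physical constants used throughout the package
#'
#' Single source of truth for unit conversions.  Internal units are fixed:
#' masses in amu, lengths in Angstrom, vibrational frequencies in cm^-1
#' (wavenumbers), energies in eV.  Every conversion between these and SI
#' goes through the constants returned here, so there is exactly one place
#' where a unit bug could live.
#'
#' @return A list with components:
#'   \describe{
#'     \item{hbar}{reduced Planck constant, J s}
#'     \item{c_cm}{speed of light, cm/s (so \code{2*pi*c_cm*omega} is the
#'       angular frequency in rad/s of a mode with wavenumber \code{omega})}
#'     \item{amu_to_kg}{atomic mass unit, kg}
#'     \item{wavenumber_to_eV}{energy of one wavenumber quantum, eV per cm^-1
#'       (\eqn{hc} in eV cm)}
#'     \item{angstrom_to_m}{1e-10}
#'   }
#' @examples
#' k <- physical_constants()
#' k$wavenumber_to_eV * 2149  # C=N stretch quantum of HCN in eV
#' @export
physical_constants <- function() {
  list(
    # hbar and the wavenumber factor are both derived from the exact SI
    # h = 6.62607015e-34 at full double precision, so hbar*omega_angular
    # and (hc/e)*omega agree to machine epsilon and the harmonic partition
    # identity closes exactly
    hbar            = 1.054571817646156e-34,  # J s, h / 2pi
    c_cm            = 2.99792458e10,          # cm / s (exact)
    amu_to_kg       = 1.66053906660e-27,      # kg
    wavenumber_to_eV = 1.239841984332003e-4,  # eV per cm^-1, hc / e
    angstrom_to_m   = 1e-10
  )
}

# angular frequency (rad/s) of a wavenumber in cm^-1
.omega_angular <- function(omega_cm1) {
  k <- physical_constants()
  2 * pi * k$c_cm * omega_cm1
}

# (amu^1/2 Angstrom)^2 -> kg m^2
.dq2_to_si <- function(dq2) {
  k <- physical_constants()
  dq2 * k$amu_to_kg * k$angstrom_to_m^2
}
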