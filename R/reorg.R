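#' Huang-Rhys factor of a displaced harmonic mode
#'
#' The Huang-Rhys factor \eqn{\bar S = \omega \Delta Q^2 / (2\hbar)}
#' measures the electron-vibrational coupling of one normal mode: the mean
#' number of vibrational quanta excited by a vertical electronic
#' transition.  \code{omega_cm1} is the mode wavenumber (converted
#' internally to the angular frequency \eqn{2\pi c \tilde\omega}) and
#' \code{delta_q} the normal-mode displacement between the two electronic
#' minima in amu^1/2 Angstrom.
#'
#' @param omega_cm1 wavenumber(s), cm^-1, positive.
#' @param delta_q displacement(s), amu^1/2 Angstrom.
#' @return Dimensionless \eqn{\bar S \ge 0}, vectorized.
#' @examples
#' huang_rhys(1000, 1)      # ~14.83
#' huang_rhys(2149, delta_q_from_huang_rhys(2149, 1.978))  # 1.978
#' @export
huang_rhys <- function(omega_cm1, delta_q) {
  if (any(omega_cm1 <= 0)) .stopf("omega_cm1 must be positive")
  k <- physical_constants()
  .omega_angular(omega_cm1) * .dq2_to_si(delta_q^2) / (2 * k$hbar)
}

#' Displacement that produces a given Huang-Rhys factor
#'
#' Algebraic inverse of [huang_rhys()]:
#' \eqn{|\Delta Q| = \sqrt{2\hbar \bar S/\omega}}, returned in
#' amu^1/2 Angstrom (sign is not recoverable from \eqn{\bar S}).
#'
#' @param omega_cm1 wavenumber(s), cm^-1, positive.
#' @param s Huang-Rhys factor(s), >= 0.
#' @return \eqn{|\Delta Q|} in amu^1/2 Angstrom.
#' @export
delta_q_from_huang_rhys <- function(omega_cm1, s) {
  if (any(omega_cm1 <= 0)) .stopf("omega_cm1 must be positive")
  if (any(s < 0)) .stopf("s must be >= 0")
  k <- physical_constants()
  dq2_si <- 2 * k$hbar * s / .omega_angular(omega_cm1)
  sqrt(dq2_si / (k$amu_to_kg * k$angstrom_to_m^2))
}

#' Per-mode reorganization energy
#'
#' \eqn{\lambda_j = \hbar\omega_j \bar S_j}: the energy a mode releases as
#' the nuclei relax after a vertical transition, i.e. its share of the
#' intramolecular reorganization energy.
#'
#' @param omega_cm1 wavenumber(s), cm^-1, positive.
#' @param s Huang-Rhys factor(s), >= 0.
#' @return \eqn{\lambda_j} in eV, vectorized.
#' @examples
#' mode_reorg_energy(2149, 1.978)  # 0.527 eV, the HCN C=N stretch
#' @export
mode_reorg_energy <- function(omega_cm1, s) {
  if (any(omega_cm1 <= 0)) .stopf("omega_cm1 must be positive")
  if (any(s < 0)) .stopf("s must be >= 0")
  physical_constants()$wavenumber_to_eV * omega_cm1 * s
}

#' Adiabatic four-point reorganization energies
#'
#' Computes the relaxation energies of the two adiabatic surfaces from
#' four energies: \eqn{\lambda_N = E_N(rel) - E_N} (neutral surface,
#' evaluated at the charged geometry minus its own minimum),
#' \eqn{\lambda_C = E_C(rel) - E_C}, and their sum, the total
#' intramolecular reorganization energy \eqn{\lambda_i}.
#'
#' @param e_n neutral-state energy at the neutral minimum, eV.
#' @param e_n_rel neutral-state energy at the charged-state minimum, eV.
#' @param e_c charged-state energy at the charged minimum, eV.
#' @param e_c_rel charged-state energy at the neutral-state minimum, eV.
#' @return A list with \code{lambda_n}, \code{lambda_c}, \code{lambda_i}
#'   (all eV).
#' @export
adiabatic_reorg <- function(e_n, e_n_rel, e_c, e_c_rel) {
  lambda_n <- e_n_rel - e_n
  lambda_c <- e_c_rel - e_c
  if (lambda_n < 0)
    .stopf("negative neutral relaxation energy (%.3g eV): E_N(rel) < E_N, inputs inconsistent with E_N being the surface minimum", lambda_n)
  if (lambda_c < 0)
    .stopf("negative charged relaxation energy (%.3g eV): E_C(rel) < E_C, inputs inconsistent with E_C being the surface minimum", lambda_c)
  list(lambda_n = lambda_n, lambda_c = lambda_c,
       lambda_i = lambda_n + lambda_c)
}

#' Activation energy of a single-mode electron-transfer channel
#'
#' High-temperature parabolic dependence of the activation energy on the
#' number of phonons \eqn{\upsilon} excited in the accepting mode:
#' \eqn{E_A = \hbar\omega(\upsilon - \bar S)^2 / (4\bar S)}.  The channel
#' is activationless at \eqn{\upsilon = \bar S}.
#'
#' @param omega_cm1 wavenumber, cm^-1, positive.
#' @param s Huang-Rhys factor, > 0 (the formula is singular at 0).
#' @param upsilon phonon count (need not be an integer; the parabola is
#'   continuous in \eqn{\upsilon}).
#' @return \eqn{E_A} in eV.
#' @export
activation_energy <- function(omega_cm1, s, upsilon) {
  if (any(omega_cm1 <= 0)) .stopf("omega_cm1 must be positive")
  if (any(s <= 0))
    .stopf("activation energy is singular at s = 0; need s > 0")
  physical_constants()$wavenumber_to_eV * omega_cm1 * (upsilon - s)^2 / (4 * s)
}

#' Most likely phonon count of a vibronic transition
#'
#' The activationless channel sits at \eqn{\upsilon = \bar S}; the nearest
#' integer phonon number (rounded half away from zero) is the count of
#' quanta the transition is expected to excite.
#'
#' @param s Huang-Rhys factor(s), >= 0.
#' @return Integer phonon count(s).
#' @examples
#' phonon_estimate(1.978)  # 2
#' phonon_estimate(1.594)  # 2
#' @export
phonon_estimate <- function(s) {
  if (any(s < 0)) .stopf("s must be >= 0")
  # half-away-from-zero, not banker's rounding
  as.integer(floor(s + 0.5))
}

#' Build a Huang-Rhys mode table for a pair of electronic states
#'
#' Runs the full projection pipeline for one basis: aligns the two
#' geometries (mass-weighted Kabsch), projects the inter-minimum
#' displacement onto the chosen state's normal modes, converts each
#' \eqn{\Delta Q_j} to a Huang-Rhys factor and a per-mode reorganization
#' energy, and returns the rows sorted by frequency.
#'
#' @param state_neutral,state_charged the two \code{state_model}s.
#' @param basis \code{"neutral"} (project onto the neutral state's modes)
#'   or \code{"charged"}.
#' @return A \code{mode_table} with one row per mode of the basis state.
#' @export
build_mode_table <- function(state_neutral, state_charged,
                             basis = c("neutral", "charged")) {
  basis <- match.arg(basis)
  disp <- normal_mode_displacements(state_neutral, state_charged, basis)
  b <- if (basis == "neutral") state_neutral else state_charged
  s <- huang_rhys(b$frequencies_cm1, disp$delta_q)
  mode_table(b$frequencies_cm1, s, state_basis = basis)
}

#' Partition the reorganization energy of a state pair over modes
#'
#' Builds both basis mode tables and sums their per-mode reorganization
#' energies into \eqn{\lambda_N}, \eqn{\lambda_C} and
#' \eqn{\lambda_i = \lambda_N + \lambda_C}.  If both models carry
#' adiabatic energies, the four-point values are reported alongside for
#' comparison (they agree exactly only on harmonic surfaces).
#'
#' @param state_neutral,state_charged the two \code{state_model}s.
#' @return A list with \code{lambda_n}, \code{lambda_c}, \code{lambda_i}
#'   (mode sums, eV), \code{table_neutral}, \code{table_charged}, and
#'   \code{adiabatic} (the four-point list, or NULL).
#' @export
reorg_summary <- function(state_neutral, state_charged) {
  tn <- build_mode_table(state_neutral, state_charged, "neutral")
  tc <- build_mode_table(state_neutral, state_charged, "charged")
  adi <- NULL
  if (!is.null(state_neutral$energy_eV) &&
      !is.null(state_neutral$energy_at_other_minimum_eV) &&
      !is.null(state_charged$energy_eV) &&
      !is.null(state_charged$energy_at_other_minimum_eV)) {
    adi <- adiabatic_reorg(state_neutral$energy_eV,
                           state_neutral$energy_at_other_minimum_eV,
                           state_charged$energy_eV,
                           state_charged$energy_at_other_minimum_eV)
  }
  list(lambda_n = sum(tn$lambda_eV),
       lambda_c = sum(tc$lambda_eV),
       lambda_i = sum(tn$lambda_eV) + sum(tc$lambda_eV),
       table_neutral = tn, table_charged = tc,
       adiabatic = adi)
}
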