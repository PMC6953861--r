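# Synthetic fixture generators with analytically known ground truth.
# These stand in for quantum-chemistry-derived inputs: displaced harmonic
# oscillators whose Huang-Rhys factors follow in closed form, so every
# pipeline stage can be regression-tested without external data.

# run expr with a locally seeded RNG, restoring global state afterwards
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Displaced-diatomic fixture with closed-form Huang-Rhys factor
#'
#' Two harmonic states of a diatomic sharing one stretch mode (the
#' reduced-mass-weighted bond direction), with equilibrium bond lengths
#' differing by \code{delta_r}.  The projected displacement is
#' \eqn{|\Delta Q| = \sqrt{\mu}\,\Delta r} with \eqn{\mu} the reduced
#' mass, so the exact Huang-Rhys factor
#' \eqn{\bar S = \omega\,\mu\,\Delta r^2/(2\hbar)} is attached as ground
#' truth.
#'
#' @param m1,m2 atomic masses, amu.
#' @param frequency_cm1 stretch wavenumber, cm^-1.
#' @param delta_r bond-length change between the two minima, Angstrom.
#' @param bond_length neutral-state bond length, Angstrom.
#' @param elements length-2 element symbols (cosmetic).
#' @return A list with \code{neutral}, \code{charged} (both
#'   \code{state_model}, the charged one labelled anion), and
#'   \code{expected_s}, the analytic Huang-Rhys factor.
#' @export
make_displaced_diatomic <- function(m1, m2, frequency_cm1, delta_r,
                                    bond_length = 1.1,
                                    elements = c("X", "Y")) {
  if (m1 <= 0 || m2 <= 0) .stopf("masses must be positive")
  if (frequency_cm1 <= 0) .stopf("frequency must be positive")
  masses <- c(m1, m2)
  mt <- m1 + m2
  mu <- m1 * m2 / mt
  # stretch mode in mass-weighted coordinates (orthonormal, COM-preserving)
  L <- matrix(c(0, 0, -sqrt(m2 / mt), 0, 0, sqrt(m1 / mt)), ncol = 1L)
  geom_n <- c(0, 0, 0, 0, 0, bond_length)
  # displace both atoms to keep the centre of mass fixed
  geom_c <- c(0, 0, -m2 / mt * delta_r, 0, 0, bond_length + m1 / mt * delta_r)
  mk <- function(label, charge, geom) state_model(
    state_label = label, charge = charge, elements = elements,
    masses_amu = masses, geometry_angstrom = geom,
    frequencies_cm1 = frequency_cm1, mode_matrix = L, linear = TRUE)
  list(neutral = mk("neutral", 0L, geom_n),
       charged = mk("anion", -1L, geom_c),
       expected_s = huang_rhys(frequency_cm1, sqrt(mu) * delta_r))
}

#' Random polyatomic state pair with prescribed per-mode Huang-Rhys factors
#'
#' Parameter-recovery harness: draws a random (seeded) non-degenerate
#' geometry, builds an orthonormal mode matrix spanning exactly the
#' complement of the translation/rotation subspace (so projections are
#' free of rigid-body contamination by construction), draws frequencies
#' uniformly in [300, 3500] cm^-1, and displaces the second state's
#' geometry along the modes so that the projection pipeline recovers
#' exactly the requested \code{s_targets}.
#'
#' @param n_atoms number of atoms, >= 3.
#' @param seed integer seed; same seed and parameters give a bit-identical
#'   fixture.
#' @param s_targets Huang-Rhys factors, length 3*n_atoms - 6, all >= 0.
#' @return A list with \code{neutral}, \code{charged}
#'   (\code{state_model}s sharing the mode matrix and frequencies),
#'   \code{s_targets}, and \code{delta_q} (the signed prescribed
#'   displacements, amu^1/2 Angstrom).
#' @export
make_random_polyatomic <- function(n_atoms, seed, s_targets) {
  if (n_atoms < 3L) .stopf("need n_atoms >= 3")
  nv <- 3L * n_atoms - 6L
  if (length(s_targets) != nv)
    .stopf("s_targets must have length 3n-6 = %d, got %d", nv,
           length(s_targets))
  if (any(s_targets < 0)) .stopf("s_targets must be >= 0")
  .with_seed(seed, {
    masses <- stats::runif(n_atoms, 1, 20)
    # spread-out random geometry, COM at the origin
    geom <- matrix(stats::runif(3L * n_atoms, -2, 2), ncol = 3L)
    geom <- sweep(geom, 2L, colSums(geom * masses) / sum(masses))
    sm3 <- sqrt(rep(masses, each = 3L))
    # translation + rotation generators in mass-weighted coordinates
    TR <- matrix(0, 3L * n_atoms, 6L)
    for (k in 1:3) TR[seq(k, 3L * n_atoms, by = 3L), k] <- sqrt(masses)
    for (a in seq_len(n_atoms)) {
      idx <- (3L * (a - 1L) + 1L):(3L * a)
      r <- geom[a, ]
      TR[idx, 4L] <- sqrt(masses[a]) * c(0, -r[3L], r[2L])   # about x
      TR[idx, 5L] <- sqrt(masses[a]) * c(r[3L], 0, -r[1L])   # about y
      TR[idx, 6L] <- sqrt(masses[a]) * c(-r[2L], r[1L], 0)   # about z
    }
    # orthonormal basis of the vibrational complement, randomly rotated
    qtr <- qr.Q(qr(TR))
    rand <- matrix(stats::rnorm(3L * n_atoms * nv), ncol = nv)
    vib <- rand - qtr %*% crossprod(qtr, rand)
    L <- qr.Q(qr(vib))[, seq_len(nv), drop = FALSE]
    freqs <- sort(stats::runif(nv, 300, 3500))
    dq <- delta_q_from_huang_rhys(freqs, s_targets)
    # displace the second state along the modes: x2 = x1 + M^(-1/2) L dq
    geom1 <- as.numeric(t(geom))
    geom2 <- geom1 + as.numeric(L %*% dq) / sm3
    list(
      neutral = state_model("neutral", 0L,
                            elements = rep("X", n_atoms), masses_amu = masses,
                            geometry_angstrom = geom1,
                            frequencies_cm1 = freqs, mode_matrix = L),
      charged = state_model("anion", -1L,
                            elements = rep("X", n_atoms), masses_amu = masses,
                            geometry_angstrom = geom2,
                            frequencies_cm1 = freqs, mode_matrix = L),
      s_targets = s_targets, delta_q = dq)
  })
}

#' Published per-mode table for hydrogen cyanide
#'
#' The printed HCN reference values: three modes per state (bend, C=N
#' stretch, C-H stretch) with their wavenumbers, Huang-Rhys factors and
#' per-mode reorganization energies, for the neutral and the anionic
#' state.  The anionic C-H row is known to be internally inconsistent in
#' its last printed digit (\eqn{\hbar\omega\bar S} recomputes to 0.0124
#' eV against the printed 0.013); the printed value is preserved and the
#' loader flags it.
#'
#' @return A list with \code{neutral} and \code{anionic}
#'   \code{mode_table}s.
#' @export
table1_hcn <- function() {
  neutral <- mode_table(
    omega_cm1 = c(778, 2149, 3500),
    huang_rhys = c(0, 1.978, 0.084),
    lambda_eV = c(0, 0.527, 0.036),
    assignment = c("bend", "C=N stretch", "C-H stretch"),
    state_basis = "neutral")
  anionic <- suppressWarnings(mode_table(
    omega_cm1 = c(696, 1704, 3446),
    huang_rhys = c(0, 1.594, 0.029),
    lambda_eV = c(0, 0.337, 0.013),
    assignment = c("bend", "C=N stretch", "C-H stretch"),
    state_basis = "charged"))
  list(neutral = neutral, anionic = anionic)
}

#' Synthetic isotopologue emission-table pairs
#'
#' Small per-mode (frequency, Huang-Rhys) tables emulating the reported
#' deuteration behaviour of two ketone odorants, for exercising the
#' comparison module: the acetophenone-like pair shares all bands up to a
#' single ~200 cm^-1 shift of one skeletal mode, while the
#' cyclopentadecanone-like pair shifts its strong C-H/C-D stretch band by
#' the full ~1/sqrt(2) isotope factor (~800 cm^-1), making the
#' isotopologues spectrally distinguishable.  These are synthetic
#' stand-ins constructed in-package, not published supplementary data.
#'
#' @return A list of four \code{mode_table}s (charged basis):
#'   \code{acetophenone}, \code{acetophenone_d}, \code{cyclopentadecanone},
#'   \code{cyclopentadecanone_d}.
#' @export
synthetic_isotopologue_tables <- function() {
  mk <- function(omega, s) mode_table(omega, s, state_basis = "charged")
  list(
    # three-band pattern; deuteration moves only the mid skeletal band
    acetophenone       = mk(c(480, 1014, 1630), c(0.177, 0.188, 0.30)),
    acetophenone_d     = mk(c(450,  811, 1630), c(0.159, 0.210, 0.30)),
    # strong C-H stretch band that deuteration shifts by ~1/sqrt(2)
    cyclopentadecanone   = mk(c(500, 1440, 2900), c(0.20, 0.25, 0.60)),
    cyclopentadecanone_d = mk(c(480, 1180, 2090), c(0.20, 0.25, 0.60))
  )
}
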