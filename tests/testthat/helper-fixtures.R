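# shared test helpers; all fixtures are built in code

# apply a rigid rotation (angle about axis z/x/y) plus translation to a
# state model: geometry and normal-mode vectors transform covariantly
rigid_transform <- function(model, angle, axis = "z", shift = c(0, 0, 0)) {
  ca <- cos(angle); sa <- sin(angle)
  R <- switch(axis,
    z = matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, byrow = TRUE),
    x = matrix(c(1, 0, 0, 0, ca, -sa, 0, sa, ca), 3, byrow = TRUE),
    y = matrix(c(ca, 0, sa, 0, 1, 0, -sa, 0, ca), 3, byrow = TRUE))
  G <- matrix(model$geometry_angstrom, ncol = 3, byrow = TRUE)
  G <- sweep(G %*% t(R), 2, -shift)
  model$geometry_angstrom <- as.numeric(t(G))
  for (a in seq_along(model$masses_amu)) {
    idx <- (3 * (a - 1) + 1):(3 * a)
    model$mode_matrix[idx, ] <- R %*% model$mode_matrix[idx, , drop = FALSE]
  }
  model
}

# independent oracle: energy (eV) of a harmonic surface displaced by
# delta_q (amu^1/2 Angstrom) per mode, E = sum_j 1/2 omega_ang_j^2 dQ_j^2,
# written with inline SI constants so it shares nothing with the package's
# conversion path beyond physical reality
quadratic_relaxation_energy_eV <- function(omega_cm1, delta_q) {
  w <- 2 * pi * 2.99792458e10 * omega_cm1          # rad/s
  dq2 <- delta_q^2 * 1.66053906660e-27 * 1e-20     # kg m^2
  sum(0.5 * w^2 * dq2) / 1.602176634e-19           # J -> eV
}

# orthonormal vibrational basis (3n-6 columns) for a given geometry/mass
# set: complement of the translation/rotation generators
vib_basis <- function(masses, geom_flat) {
  n <- length(masses)
  G <- matrix(geom_flat, ncol = 3, byrow = TRUE)
  G <- sweep(G, 2, colSums(G * masses) / sum(masses))
  TR <- matrix(0, 3 * n, 6)
  for (k in 1:3) TR[seq(k, 3 * n, by = 3), k] <- sqrt(masses)
  for (a in seq_len(n)) {
    idx <- (3 * (a - 1) + 1):(3 * a)
    r <- G[a, ]
    TR[idx, 4] <- sqrt(masses[a]) * c(0, -r[3], r[2])
    TR[idx, 5] <- sqrt(masses[a]) * c(r[3], 0, -r[1])
    TR[idx, 6] <- sqrt(masses[a]) * c(-r[2], r[1], 0)
  }
  qtr <- qr.Q(qr(TR))
  set.seed(7)
  rand <- matrix(rnorm(3 * n * (3 * n - 6)), ncol = 3 * n - 6)
  vib <- rand - qtr %*% crossprod(qtr, rand)
  qr.Q(qr(vib))[, seq_len(3 * n - 6), drop = FALSE]
}
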