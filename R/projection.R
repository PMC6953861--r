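#' Mass-weighted least-squares superposition of two state geometries
#'
#' The normal-mode projection formulas presuppose that the two equilibrium
#' geometries sit in a common body-fixed frame; quantum-chemistry outputs
#' rarely do.  This aligns \code{moving} onto \code{reference} by the
#' Kabsch algorithm on mass-weighted coordinates: both structures are
#' shifted to their centres of mass and the proper rotation minimizing the
#' mass-weighted RMSD is applied.  This realizes the Eckart conditions
#' (zero net mass-weighted translation; zero mass-weighted "angular
#' momentum" of the displacement at the optimum), so the residual
#' displacement lies in the vibrational subspace up to harmonic order.
#' Reflections are never applied: if the best superposition requires an
#' improper operation the geometries describe different stereoisomers and
#' an error is raised.
#'
#' @param reference,moving \code{state_model}s with identical elements in
#'   identical order.
#' @return A list with \code{geometry} (the aligned moving geometry as a
#'   flat 3n vector, Angstrom, expressed in the reference COM frame),
#'   \code{reference_geometry} (reference geometry in the same frame),
#'   \code{rotation} (3x3), and \code{rmsd} (mass-weighted RMSD,
#'   Angstrom).
#' @export
align_structures <- function(reference, moving) {
  stopifnot(inherits(reference, "state_model"), inherits(moving, "state_model"))
  if (length(reference$elements) != length(moving$elements) ||
      !all(reference$elements == moving$elements))
    .stopf("element-order mismatch between the two structures")
  m <- reference$masses_amu
  P <- .geom_matrix(reference)
  Q <- .geom_matrix(moving)
  wp <- colSums(P * m) / sum(m)
  wq <- colSums(Q * m) / sum(m)
  P <- sweep(P, 2L, wp)
  Q <- sweep(Q, 2L, wq)
  # Kabsch on mass-weighted coordinates: C = sum_i m_i q_i p_i^T
  C <- t(Q * m) %*% P
  sv <- svd(C)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d < 0) {
    # proper-rotation correction; if the corrected fit is materially worse
    # than the improper one the structures are mirror images
    improper_rmsd <- sqrt(sum(m * rowSums((Q %*% sv$u %*% t(sv$v) - P)^2)) / sum(m))
    R <- sv$v %*% diag(c(1, 1, -1)) %*% t(sv$u)
    proper_rmsd <- sqrt(sum(m * rowSums((Q %*% t(R) - P)^2)) / sum(m))
    if (proper_rmsd > improper_rmsd + 1e-6)
      .stopf("best superposition requires a reflection (proper RMSD %.4g vs improper %.4g); refusing to mirror the structure",
             proper_rmsd, improper_rmsd)
  } else {
    R <- sv$v %*% t(sv$u)
  }
  Qa <- Q %*% t(R)
  rmsd <- sqrt(sum(m * rowSums((Qa - P)^2)) / sum(m))
  list(geometry = as.numeric(t(Qa)),
       reference_geometry = as.numeric(t(P)),
       rotation = R, rmsd = rmsd)
}

#' Project the inter-state geometry change onto normal modes
#'
#' After alignment, the displacement between the two equilibrium
#' geometries is projected onto the mass-weighted normal modes of the
#' chosen basis state: \eqn{\Delta Q = L^T M^{1/2} \Delta x}, in amu^1/2
#' Angstrom.  Sign convention: the neutral basis projects (charged minus
#' neutral); the charged basis projects (neutral minus charged).  The
#' Huang-Rhys factors downstream depend only on \eqn{\Delta Q^2}, so the
#' convention never changes spectra.
#'
#' Any part of the mass-weighted displacement outside the span of the mode
#' matrix (residual rotation/translation contamination, or curvilinear
#' character the rectilinear modes cannot express) is reported as
#' \code{residual_norm}; if it exceeds 1% of the total displacement norm a
#' warning is emitted rather than silently dropping it.
#'
#' @param state_neutral,state_charged aligned automatically; must share
#'   elements and atom order.
#' @param basis \code{"neutral"} or \code{"charged"}: whose mode matrix
#'   projects.
#' @return A list of class \code{displacement_result}: \code{basis},
#'   \code{delta_q} (length n_v, amu^1/2 Angstrom),
#'   \code{aligned_displacement} (3n Cartesian displacement after
#'   alignment, Angstrom), \code{residual_norm} and
#'   \code{displacement_norm} (mass-weighted, amu^1/2 Angstrom).
#' @export
normal_mode_displacements <- function(state_neutral, state_charged,
                                      basis = c("neutral", "charged")) {
  basis <- match.arg(basis)
  b <- if (basis == "neutral") state_neutral else state_charged
  other <- if (basis == "neutral") state_charged else state_neutral
  al <- align_structures(b, other)
  dx <- al$geometry - al$reference_geometry         # x_other - x_basis
  sm <- sqrt(rep(b$masses_amu, each = 3L))
  mw <- sm * dx                                     # M^(1/2) dx
  dq <- as.numeric(crossprod(b$mode_matrix, mw))
  resid <- mw - b$mode_matrix %*% dq
  rn <- sqrt(sum(resid^2))
  dn <- sqrt(sum(mw^2))
  if (dn > 0 && rn > 0.01 * dn)
    .warnf("%.1f%% of the mass-weighted displacement lies outside the span of the %s-state modes (residual %.3g of %.3g amu^1/2 A)",
           100 * rn / dn, basis, rn, dn)
  structure(list(basis = basis, delta_q = dq,
                 aligned_displacement = dx,
                 residual_norm = rn, displacement_norm = dn),
            class = "displacement_result")
}

#' Duschinsky rotation matrix between two electronic states
#'
#' The normal modes of one electronic state are generally a rotated
#' mixture of the other state's modes: \eqn{Q' = J Q + \Delta Q} with
#' \eqn{J = (L')^T L}, the prime marking the initial state.  For
#' rectilinear orthonormal mode matrices of a common atom set J is
#' orthogonal.  The displacement vector is returned in the final-state
#' basis.  Modes whose largest off-diagonal |J| entry exceeds 0.3 are
#' listed as strongly mixed; the spectral model downstream neglects this
#' mixing (J = I in the Franck-Condon factors), so the diagnostics say how
#' much that approximation discards.
#'
#' @param state_initial,state_final \code{state_model}s with equal mode
#'   counts; geometries are aligned internally (final state is the
#'   reference frame).
#' @return A list of class \code{duschinsky_result}: \code{j_matrix}
#'   (n_v x n_v), \code{delta_q} (final-state basis, amu^1/2 Angstrom),
#'   and \code{diagnostics}, a data frame with per-mode
#'   \code{max_offdiag} and \code{mixing_fraction}
#'   (\eqn{1 - J_{jj}^2}).
#' @export
duschinsky_matrix <- function(state_initial, state_final) {
  stopifnot(inherits(state_initial, "state_model"),
            inherits(state_final, "state_model"))
  nv <- length(state_final$frequencies_cm1)
  if (length(state_initial$frequencies_cm1) != nv)
    .stopf("unequal mode counts: initial %d, final %d",
           length(state_initial$frequencies_cm1), nv)
  al <- align_structures(state_final, state_initial)
  # rotate the initial state's mode matrix into the common frame:
  # Cartesian rotation R applied per atom to each mode column
  Li <- state_initial$mode_matrix
  n <- length(state_initial$elements)
  Lrot <- Li
  for (a in seq_len(n)) {
    idx <- (3L * (a - 1L) + 1L):(3L * a)
    Lrot[idx, ] <- al$rotation %*% Li[idx, , drop = FALSE]
  }
  J <- crossprod(Lrot, state_final$mode_matrix)     # (L')^T L
  # displacement in the final-state basis: L^T M^(1/2) (x'(0) - x(0))
  sm <- sqrt(rep(state_final$masses_amu, each = 3L))
  dq <- as.numeric(crossprod(state_final$mode_matrix,
                             sm * (al$geometry - al$reference_geometry)))
  offdiag <- abs(J); diag(offdiag) <- 0
  diagnostics <- data.frame(
    mode = seq_len(nv),
    omega_cm1 = state_final$frequencies_cm1,
    max_offdiag = apply(offdiag, 2L, max),
    mixing_fraction = 1 - diag(J)^2
  )
  structure(list(j_matrix = J, delta_q = dq,
                 diagnostics = diagnostics,
                 mixed_modes = which(diagnostics$max_offdiag > 0.3)),
            class = "duschinsky_result")
}

#' @export
print.duschinsky_result <- function(x, ...) {
  nv <- nrow(x$j_matrix)
  cat(sprintf("Duschinsky rotation: %d x %d mode-mixing matrix\n", nv, nv))
  if (length(x$mixed_modes))
    cat(sprintf("  strongly mixed modes (max |J| off-diagonal > 0.3): %s\n",
                paste(x$mixed_modes, collapse = ", ")))
  else cat("  no strongly mixed modes (all off-diagonal |J| <= 0.3)\n")
  invisible(x)
}
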