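# Franck-Condon factors for a displaced harmonic oscillator.
#
# Closed forms use the generalized Laguerre polynomials; the quadrature
# oracle integrates the Hermite-function wavefunctions directly and is the
# module's independent correctness check.

# generalized Laguerre polynomial L_n^(a)(x) by the stable three-term
# recurrence; exact for the small n used in vibronic progressions
.genlaguerre <- function(n, a, x) {
  if (n == 0L) return(rep(1, length(x)))
  lm1 <- rep(1, length(x))          # L_0
  l <- 1 + a - x                    # L_1
  if (n == 1L) return(l)
  for (k in 1L:(n - 1L)) {
    lp1 <- ((2 * k + 1 + a - x) * l - (k + a) * lm1) / (k + 1)
    lm1 <- l
    l <- lp1
  }
  l
}

#' Franck-Condon factor of a 0 -> upsilon transition (Poisson limit)
#'
#' For transitions from the vibrational ground state of a displaced
#' harmonic oscillator the Franck-Condon factors reduce to the Poisson
#' distribution with mean equal to the Huang-Rhys factor:
#' \eqn{FCF(0,\upsilon) = e^{-\bar S}\bar S^{\upsilon}/\upsilon!}.
#'
#' @param s Huang-Rhys factor, >= 0.
#' @param upsilon final phonon number(s), non-negative integer(s).
#' @return Probabilities in [0, 1], vectorized over \code{upsilon}.
#' @examples
#' fcf_poisson(1.594, 2)     # strongest line of the HCN anion progression
#' sum(fcf_poisson(2, 0:50)) # 1: the progression is normalized
#' @export
fcf_poisson <- function(s, upsilon) {
  if (length(s) != 1L || !is.finite(s) || s < 0) .stopf("s must be a single value >= 0")
  if (any(upsilon < 0) || any(upsilon != round(upsilon)))
    .stopf("upsilon must be non-negative integer(s)")
  # via logs so large upsilon cannot overflow the factorial
  if (s == 0) return(as.numeric(upsilon == 0))
  exp(-s + upsilon * log(s) - .lfact(upsilon))
}

#' Franck-Condon factor between arbitrary phonon levels
#'
#' Squared overlap of two harmonic-oscillator eigenstates whose potentials
#' are displaced by the Huang-Rhys factor \code{s}:
#' \deqn{FCF(\mu,\upsilon) = e^{-\bar S}\,\bar S^{\upsilon-\mu}\,
#'   \frac{\mu!}{\upsilon!}\,[L_\mu^{(\upsilon-\mu)}(\bar S)]^2,\qquad
#'   \upsilon \ge \mu,}
#' with \eqn{L} a generalized Laguerre polynomial; for
#' \eqn{\upsilon < \mu} the symmetry \eqn{FCF(\mu,\upsilon) =
#' FCF(\upsilon,\mu)} of the squared overlap is used.  At \eqn{\mu = 0}
#' this reduces to [fcf_poisson()].  Factorial ratios go through
#' log-gamma, so large quantum numbers do not overflow.
#'
#' @param s Huang-Rhys factor, >= 0.
#' @param mu initial phonon number, non-negative integer.
#' @param upsilon final phonon number, non-negative integer.
#' @return Probability in [0, 1].
#' @export
fcf_general <- function(s, mu, upsilon) {
  if (length(s) != 1L || !is.finite(s) || s < 0) .stopf("s must be a single value >= 0")
  if (!.is_count(mu) || !.is_count(upsilon))
    .stopf("mu and upsilon must be non-negative integers")
  if (upsilon < mu) { tmp <- mu; mu <- upsilon; upsilon <- tmp }
  if (s == 0) return(as.numeric(mu == upsilon))
  d <- upsilon - mu
  lag <- .genlaguerre(mu, d, s)
  exp(-s + d * log(s) + .lfact(mu) - .lfact(upsilon)) * lag^2
}

#' Franck-Condon factor by numeric quadrature (independent oracle)
#'
#' Evaluates \eqn{|\langle\chi_\mu(q - d)|\chi_\upsilon(q)\rangle|^2}
#' directly: Hermite-function harmonic-oscillator eigenfunctions in the
#' dimensionless coordinate, one displaced by \eqn{d = \sqrt{2\bar S}},
#' integrated by the trapezoid rule over \eqn{\pm(12 + d)} with at least
#' 2000 points.  Shares no code path with the closed forms above beyond
#' elementary arithmetic, so agreement between the two is a genuine
#' check.
#'
#' @param s Huang-Rhys factor, >= 0.
#' @param mu,upsilon phonon numbers, non-negative integers.
#' @param n_points quadrature points (>= 2000).
#' @return Probability in [0, 1].
#' @export
fcf_oracle <- function(s, mu, upsilon, n_points = 4001L) {
  if (length(s) != 1L || !is.finite(s) || s < 0) .stopf("s must be a single value >= 0")
  if (!.is_count(mu) || !.is_count(upsilon))
    .stopf("mu and upsilon must be non-negative integers")
  n_points <- max(as.integer(n_points), 2001L)
  d <- sqrt(2 * s)
  lim <- 12 + d
  q <- seq(-lim, lim + d, length.out = n_points)
  overlap <- .trapz(q, .hermite_psi(mu, q - d) * .hermite_psi(upsilon, q))
  overlap^2
}

# normalized harmonic-oscillator eigenfunction psi_n(q) =
# (2^n n! sqrt(pi))^(-1/2) H_n(q) exp(-q^2/2), with the Hermite recurrence
# folded into scaled functions to keep intermediates finite
.hermite_psi <- function(n, q) {
  # H_n by recurrence, normalization applied through logs at the end
  h_nm1 <- rep(1, length(q))        # H_0
  if (n == 0L)
    return(exp(-q^2 / 2 - 0.25 * log(pi)))
  h_n <- 2 * q                      # H_1
  if (n > 1L) for (k in 1L:(n - 1L)) {
    h_np1 <- 2 * q * h_n - 2 * k * h_nm1
    h_nm1 <- h_n
    h_n <- h_np1
  }
  lognorm <- -0.5 * (n * log(2) + .lfact(n) + 0.5 * log(pi))
  sign(h_n) * exp(lognorm + log(abs(h_n) + (h_n == 0)) - q^2 / 2) * (h_n != 0)
}

#' Franck-Condon progression from a fixed initial level
#'
#' Tabulates \eqn{FCF(\mu, \upsilon)} for \eqn{\upsilon = 0 \ldots
#' \upsilon_{max}}.  For \eqn{\mu = 0} this is the Poisson progression
#' that feeds the spectral model.
#'
#' @param s Huang-Rhys factor, >= 0.
#' @param mu initial phonon number (default 0).
#' @param upsilon_max largest final phonon number.
#' @return A data frame of class \code{fc_progression} with columns
#'   \code{upsilon} and \code{fcf}.
#' @export
fc_progression <- function(s, mu = 0L, upsilon_max = 10L) {
  if (!.is_count(upsilon_max) || upsilon_max < 1)
    .stopf("upsilon_max must be a positive integer")
  ups <- 0L:as.integer(upsilon_max)
  fcf <- if (mu == 0L) fcf_poisson(s, ups)
         else vapply(ups, function(u) fcf_general(s, mu, u), numeric(1L))
  out <- data.frame(upsilon = ups, fcf = fcf)
  attr(out, "s") <- s
  attr(out, "mu") <- as.integer(mu)
  class(out) <- c("fc_progression", "data.frame")
  out
}
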