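#' Fit the two-state vibronic model for a neutral/charged pair
#'
#' The central constructor: given harmonic models of a molecule's neutral
#' and charged (anion or cation) electronic states, it aligns the two
#' equilibrium geometries, projects the geometry change onto each state's
#' normal modes, computes per-mode Huang-Rhys factors and
#' reorganization-energy partitions for both bases, and the Duschinsky
#' mode-mixing diagnostics.  The result drives the electron-transfer
#' absorption and emission spectra via [absorption_spectrum()] /
#' [emission_spectrum()] or [plot.vibronic_model()].
#'
#' @param neutral \code{state_model} of the neutral state.
#' @param charged \code{state_model} of the charged state (anion or
#'   cation).
#' @return An object of class \code{vibronic_model} with components
#'   \code{neutral}, \code{charged} (the inputs), \code{table_neutral},
#'   \code{table_charged} (per-mode Huang-Rhys tables),
#'   \code{reorg} (the [reorg_summary()] list), and \code{duschinsky}
#'   (a \code{duschinsky_result}, charged state taken as initial).
#' @examples
#' fx <- make_displaced_diatomic(1, 1, 1000, 0.1)
#' vm <- vibronic_model(fx$neutral, fx$charged)
#' coef(vm)
#' @export
vibronic_model <- function(neutral, charged) {
  stopifnot(inherits(neutral, "state_model"), inherits(charged, "state_model"))
  if (neutral$state_label != "neutral")
    .stopf("first argument must be the neutral state, got '%s'",
           neutral$state_label)
  if (!charged$state_label %in% c("anion", "cation"))
    .stopf("second argument must be an anion or cation state, got '%s'",
           charged$state_label)
  reorg <- reorg_summary(neutral, charged)
  dus <- if (length(neutral$frequencies_cm1) == length(charged$frequencies_cm1))
    duschinsky_matrix(charged, neutral) else NULL
  structure(list(neutral = neutral, charged = charged,
                 table_neutral = reorg$table_neutral,
                 table_charged = reorg$table_charged,
                 reorg = reorg, duschinsky = dus),
            class = "vibronic_model")
}

#' @export
print.vibronic_model <- function(x, ...) {
  cat(sprintf("Two-state vibronic model: %s / %s, %d atoms\n",
              x$neutral$state_label, x$charged$state_label,
              length(x$neutral$elements)))
  cat(sprintf("  lambda_N = %.4f eV, lambda_C = %.4f eV, lambda_i = %.4f eV\n",
              x$reorg$lambda_n, x$reorg$lambda_c, x$reorg$lambda_i))
  smax <- which.max(x$table_charged$huang_rhys)
  cat(sprintf("  strongest coupled mode (charged basis): %g cm^-1, S = %.3f (~%d phonons)\n",
              x$table_charged$omega_cm1[smax],
              x$table_charged$huang_rhys[smax],
              phonon_estimate(x$table_charged$huang_rhys[smax])))
  invisible(x)
}

#' Per-mode Huang-Rhys factors of a fitted vibronic model
#'
#' @param object a \code{vibronic_model}.
#' @param basis \code{"charged"} (default; drives the emission spectrum)
#'   or \code{"neutral"}.
#' @param ... unused.
#' @return Named numeric vector of Huang-Rhys factors, names the mode
#'   wavenumbers in cm^-1.
#' @export
coef.vibronic_model <- function(object, basis = c("charged", "neutral"),
                                ...) {
  basis <- match.arg(basis)
  tab <- if (basis == "charged") object$table_charged else object$table_neutral
  stats::setNames(tab$huang_rhys, format(tab$omega_cm1))
}

#' @export
summary.vibronic_model <- function(object, ...) {
  structure(list(model = object), class = "summary.vibronic_model")
}

#' @export
print.summary.vibronic_model <- function(x, ...) {
  m <- x$model
  print(m)
  cat("\nNeutral-basis modes (absorption):\n")
  print.data.frame(m$table_neutral, row.names = FALSE)
  cat("\nCharged-basis modes (emission):\n")
  print.data.frame(m$table_charged, row.names = FALSE)
  if (!is.null(m$duschinsky)) {
    mixed <- m$duschinsky$mixed_modes
    cat(sprintf("\nDuschinsky mixing: %s\n",
                if (length(mixed))
                  sprintf("modes %s mix strongly (max off-diagonal |J| > 0.3)",
                          paste(mixed, collapse = ", "))
                else "weak (all off-diagonal |J| <= 0.3)"))
  }
  if (!is.null(m$reorg$adiabatic)) {
    cat(sprintf("\nAdiabatic four-point check: lambda_i = %.4f eV (mode sum %.4f eV)\n",
                m$reorg$adiabatic$lambda_i, m$reorg$lambda_i))
  }
  invisible(x)
}

#' Plot the electron-transfer spectra of a vibronic model
#'
#' Draws the max-normalized absorption (neutral basis) and emission
#' (charged basis) spectra on one set of axes.
#'
#' @param x a \code{vibronic_model}.
#' @param sigma Gaussian width, cm^-1.
#' @param upsilon_max phonons per mode.
#' @param ... passed to \code{graphics::plot}.
#' @return The pair of spectra, invisibly.
#' @export
plot.vibronic_model <- function(x, sigma = 100, upsilon_max = 10L, ...) {
  ab <- absorption_spectrum(x$table_neutral, upsilon_max = upsilon_max,
                            sigma = sigma)
  em <- emission_spectrum(x$table_charged, upsilon_max = upsilon_max,
                          sigma = sigma)
  graphics::plot(ab$grid, ab$values, type = "l", col = "firebrick",
                 xlab = expression(tilde(nu)~(cm^-1)), ylab = "intensity",
                 ...)
  graphics::lines(em$grid, em$values, col = "navy")
  graphics::legend("topright", legend = c("absorption", "emission"),
                   col = c("firebrick", "navy"), lty = 1, bty = "n")
  invisible(list(absorption = ab, emission = em))
}
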