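#' Construct a harmonic model of one electronic state
#'
#' A state model bundles everything the harmonic approximation needs about
#' one electronic state of a molecule: element symbols and atomic masses,
#' the equilibrium Cartesian geometry, the harmonic wavenumbers, and the
#' mass-weighted normal-mode matrix whose columns are orthonormal
#' vibrational eigenvectors.  Optional adiabatic energies (at the state's
#' own minimum and at the partner state's minimum) support the four-point
#' reorganization-energy calculation.
#'
#' @param state_label one of \code{"neutral"}, \code{"anion"},
#'   \code{"cation"}.
#' @param charge integer net charge.
#' @param elements character vector of element symbols, length n.
#' @param masses_amu atomic masses in amu, length n, all positive.
#' @param geometry_angstrom equilibrium Cartesian coordinates, a length-3n
#'   numeric vector ordered x1,y1,z1,x2,...
#' @param frequencies_cm1 harmonic wavenumbers in cm^-1, length n_v, all
#'   positive (imaginary modes are rejected).
#' @param mode_matrix 3n x n_v mass-weighted normal-mode matrix with
#'   orthonormal columns (tolerance 1e-6).
#' @param energy_eV optional adiabatic energy at this state's own minimum.
#' @param energy_at_other_minimum_eV optional energy of this state evaluated
#'   at the partner state's equilibrium geometry.
#' @param linear logical; linear molecules have n_v = 3n-5 vibrations,
#'   nonlinear ones 3n-6.
#'
#' @return An object of class \code{state_model}.
#' @seealso [read_state_model()], [write_state_model()]
#' @export
state_model <- function(state_label, charge, elements, masses_amu,
                        geometry_angstrom, frequencies_cm1, mode_matrix,
                        energy_eV = NULL, energy_at_other_minimum_eV = NULL,
                        linear = FALSE) {
  if (!state_label %in% c("neutral", "anion", "cation"))
    .stopf("state_label must be neutral/anion/cation, got '%s'", state_label)
  n <- length(elements)
  if (length(masses_amu) != n)
    .stopf("masses_amu: expected %d masses for %d elements, got %d",
           n, n, length(masses_amu))
  if (any(!is.finite(masses_amu)) || any(masses_amu <= 0))
    .stopf("masses_amu must be strictly positive and finite")
  if (length(geometry_angstrom) != 3L * n)
    .stopf("geometry_angstrom: expected length %d (3n), got %d",
           3L * n, length(geometry_angstrom))
  mode_matrix <- as.matrix(mode_matrix)
  nv <- length(frequencies_cm1)
  nv_expected <- if (isTRUE(linear)) 3L * n - 5L else 3L * n - 6L
  if (nv != nv_expected)
    .stopf("frequencies_cm1: %d modes given but a %s molecule of %d atoms has %d (= 3n-%d)",
           nv, if (isTRUE(linear)) "linear" else "nonlinear", n,
           nv_expected, if (isTRUE(linear)) 5L else 6L)
  if (any(frequencies_cm1 <= 0))
    .stopf("frequencies_cm1: imaginary frequency (non-positive wavenumber) at mode %d",
           which(frequencies_cm1 <= 0)[1L])
  if (nrow(mode_matrix) != 3L * n || ncol(mode_matrix) != nv)
    .stopf("mode_matrix: expected %d x %d, got %d x %d",
           3L * n, nv, nrow(mode_matrix), ncol(mode_matrix))
  defect <- .max_orthonormality_defect(mode_matrix)
  if (defect > 1e-6)
    .stopf("mode_matrix: columns not orthonormal (max defect %.3g > 1e-6)",
           defect)
  structure(list(
    state_label = state_label,
    charge      = as.integer(charge),
    elements    = as.character(elements),
    masses_amu  = as.numeric(masses_amu),
    geometry_angstrom = as.numeric(geometry_angstrom),
    frequencies_cm1   = as.numeric(frequencies_cm1),
    mode_matrix = mode_matrix,
    energy_eV   = if (is.null(energy_eV)) NULL else as.numeric(energy_eV),
    energy_at_other_minimum_eV =
      if (is.null(energy_at_other_minimum_eV)) NULL
      else as.numeric(energy_at_other_minimum_eV),
    linear = isTRUE(linear)
  ), class = "state_model")
}

#' @export
print.state_model <- function(x, ...) {
  cat(sprintf("Harmonic state model: %s (charge %+d), %d atoms [%s], %d modes%s\n",
              x$state_label, x$charge, length(x$elements),
              paste(x$elements, collapse = ""),
              length(x$frequencies_cm1),
              if (x$linear) ", linear" else ""))
  cat(sprintf("  frequencies (cm^-1): %s\n",
              paste(format(x$frequencies_cm1, digits = 6), collapse = ", ")))
  if (!is.null(x$energy_eV))
    cat(sprintf("  E(min) = %.6f eV\n", x$energy_eV))
  if (!is.null(x$energy_at_other_minimum_eV))
    cat(sprintf("  E(at partner minimum) = %.6f eV\n",
                x$energy_at_other_minimum_eV))
  invisible(x)
}

# geometry as an n x 3 matrix
.geom_matrix <- function(model) {
  matrix(model$geometry_angstrom, ncol = 3L, byrow = TRUE)
}

#' Read a state model from a JSON file
#'
#' The file is a JSON object with keys \code{state_label}, \code{charge},
#' \code{elements}, \code{masses_amu}, \code{geometry_angstrom} (flat 3n
#' array, x1,y1,z1,...), \code{frequencies_cm1}, \code{modes_massweighted}
#' (row-major 3n x n_v array), optional \code{energy_eV},
#' \code{energy_at_other_minimum_eV} and \code{linear}.  All
#' \code{state_model} invariants are validated on load and violations are
#' reported with the offending field named.
#'
#' @param path path to the JSON file.
#' @return A validated \code{state_model}.
#' @export
read_state_model <- function(path) {
  if (!file.exists(path)) .stopf("state-model file not found: %s", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  required <- c("state_label", "charge", "elements", "masses_amu",
                "geometry_angstrom", "frequencies_cm1", "modes_massweighted")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    .stopf("state-model file missing field(s): %s",
           paste(missing, collapse = ", "))
  n <- length(raw$elements)
  nv <- length(raw$frequencies_cm1)
  L <- if (is.matrix(raw$modes_massweighted)) {
    # jsonlite simplifies a regular array-of-arrays to a matrix, rows = outer
    matrix(as.numeric(raw$modes_massweighted), nrow = 3L * n, ncol = nv)
  } else {
    matrix(as.numeric(unlist(raw$modes_massweighted)),
           nrow = 3L * n, ncol = nv, byrow = TRUE)
  }
  state_model(
    state_label = raw$state_label,
    charge      = raw$charge,
    elements    = raw$elements,
    masses_amu  = raw$masses_amu,
    geometry_angstrom = raw$geometry_angstrom,
    frequencies_cm1   = raw$frequencies_cm1,
    mode_matrix = L,
    energy_eV   = raw$energy_eV,
    energy_at_other_minimum_eV = raw$energy_at_other_minimum_eV,
    linear      = isTRUE(raw$linear)
  )
}

#' Write a state model to a JSON file
#'
#' Inverse of [read_state_model()]; \code{read(write(m))} reproduces the
#' model to full double precision.
#'
#' @param model a \code{state_model}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_state_model <- function(model, path) {
  stopifnot(inherits(model, "state_model"))
  out <- list(
    state_label = model$state_label,
    charge      = model$charge,
    elements    = model$elements,
    masses_amu  = model$masses_amu,
    geometry_angstrom = model$geometry_angstrom,
    frequencies_cm1   = model$frequencies_cm1,
    # row-major: one inner array per Cartesian coordinate row
    modes_massweighted = lapply(seq_len(nrow(model$mode_matrix)),
                                function(i) model$mode_matrix[i, ]),
    linear = model$linear
  )
  if (!is.null(model$energy_eV)) out$energy_eV <- model$energy_eV
  if (!is.null(model$energy_at_other_minimum_eV))
    out$energy_at_other_minimum_eV <- model$energy_at_other_minimum_eV
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
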