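#' Vibronic stick spectrum from a Huang-Rhys mode table
#'
#' Places one Poisson progression per mode: sticks at
#' \eqn{E_0 + \upsilon\,\omega_j} with weight
#' \eqn{e^{-\bar S_j}\bar S_j^{\upsilon}/\upsilon!} for
#' \eqn{\upsilon = 1 \ldots \upsilon_{max}}, plus a single 0-0 stick at
#' \eqn{E_0} carrying the product \eqn{\prod_j e^{-\bar S_j}} of all modes'
#' ground-state factors.  \code{mode = "fundamentals"} keeps only the
#' \eqn{\upsilon = 1} stick of each mode.  Cross-mode combination lines
#' (quanta in two modes at once) are not generated: each mode contributes
#' an independent single-mode ladder.
#'
#' @param table a \code{mode_table}.
#' @param upsilon_max largest phonon number per mode (>= 1).
#' @param e0 0-0 transition energy offset, cm^-1 (default 0: spectra are
#'   plotted against vibrational wavenumber relative to the 0-0 line).
#' @param mode \code{"progression"} or \code{"fundamentals"}.
#' @return An object of class \code{stick_spectrum}: a data frame with
#'   columns \code{position_cm1}, \code{weight}, \code{mode_index},
#'   \code{upsilon}, plus attributes \code{state_basis} and \code{e0}.
#' @export
stick_spectrum <- function(table, upsilon_max = 10L, e0 = 0,
                           mode = c("progression", "fundamentals")) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "mode_table"))
  if (nrow(table) == 0L) .stopf("empty mode table")
  if (!.is_count(upsilon_max) || upsilon_max < 1)
    .stopf("upsilon_max must be a positive integer")
  rows <- list()
  for (j in seq_len(nrow(table))) {
    s <- table$huang_rhys[j]
    if (s == 0) next                     # no vibronic ladder, 0-0 only
    ups <- if (mode == "progression") 1:upsilon_max else 1L
    rows[[length(rows) + 1L]] <- data.frame(
      position_cm1 = e0 + ups * table$omega_cm1[j],
      weight = fcf_poisson(s, ups),
      mode_index = j, upsilon = ups)
  }
  if (mode == "progression") {
    rows[[length(rows) + 1L]] <- data.frame(
      position_cm1 = e0, weight = exp(-sum(table$huang_rhys)),
      mode_index = 0L, upsilon = 0L)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(position_cm1 = numeric(), weight = numeric(),
                      mode_index = integer(), upsilon = integer())
  out <- out[order(out$position_cm1), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "state_basis") <- attr(table, "state_basis")
  attr(out, "e0") <- e0
  class(out) <- c("stick_spectrum", "data.frame")
  out
}

#' Gaussian convolution of a stick spectrum
#'
#' Replaces every stick by a unit-area Gaussian of standard deviation
#' \code{sigma} centred at the stick position and sums them on a
#' wavenumber grid, then normalizes.  The default width of 100 cm^-1
#' mimics the resolution attributed to biological electron-tunneling
#' detection (~400 cm^-1 band width).
#'
#' @param sticks a \code{stick_spectrum} (or any data frame with
#'   \code{position_cm1} and \code{weight}).
#' @param sigma Gaussian standard deviation, cm^-1, > 0.
#' @param grid_start,grid_stop,grid_step grid limits and spacing, cm^-1.
#' @param normalization \code{"max1"} (peak scaled to 1, the default, for
#'   cross-molecule comparability), \code{"area1"}, or \code{"none"}.
#' @return An object of class \code{convolved_spectrum}: list with
#'   \code{grid}, \code{values}, \code{sigma}, \code{normalization}.
#' @export
convolve_spectrum <- function(sticks, sigma = 100, grid_start = 0,
                              grid_stop = 4000, grid_step = 1,
                              normalization = c("max1", "area1", "none")) {
  normalization <- match.arg(normalization)
  if (sigma <= 0) .stopf("sigma must be positive")
  if (grid_step <= 0) .stopf("grid_step must be positive")
  if (grid_stop <= grid_start) .stopf("grid_stop must exceed grid_start")
  if (grid_step > sigma)
    .warnf("grid step (%g) coarser than sigma (%g): peaks may be aliased",
           grid_step, sigma)
  grid <- seq(grid_start, grid_stop, by = grid_step)
  values <- numeric(length(grid))
  for (i in seq_len(nrow(sticks))) {
    values <- values + sticks$weight[i] *
      stats::dnorm(grid, mean = sticks$position_cm1[i], sd = sigma)
  }
  values <- switch(normalization,
    max1 = if (max(values) > 0) values / max(values) else values,
    area1 = { a <- .trapz(grid, values); if (a > 0) values / a else values },
    none = values)
  structure(list(grid = grid, values = values, sigma = sigma,
                 normalization = normalization),
            class = "convolved_spectrum")
}

#' @export
print.convolved_spectrum <- function(x, ...) {
  cat(sprintf("Convolved spectrum: %d points on [%g, %g] cm^-1, sigma = %g, normalization = %s\n",
              length(x$grid), min(x$grid), max(x$grid), x$sigma,
              x$normalization))
  if (max(x$values) > 0)
    cat(sprintf("  maximum at %g cm^-1\n", x$grid[which.max(x$values)]))
  invisible(x)
}

#' @export
plot.convolved_spectrum <- function(x, ...,
                                    xlab = expression(tilde(nu)~(cm^-1)),
                                    ylab = "intensity", type = "l") {
  graphics::plot(x$grid, x$values, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

# shared builder behind absorption_spectrum / emission_spectrum
.et_spectrum <- function(table, upsilon_max, e0, sigma, grid_start,
                         grid_stop, grid_step, mode, normalization,
                         transition) {
  st <- stick_spectrum(table, upsilon_max = upsilon_max, e0 = e0, mode = mode)
  cs <- convolve_spectrum(st, sigma = sigma, grid_start = grid_start,
                          grid_stop = grid_stop, grid_step = grid_step,
                          normalization = normalization)
  cs$transition <- transition
  cs$sticks <- st
  cs
}

#' Electron-transfer absorption / emission spectra
#'
#' State conventions of the donor-bridge-acceptor picture: the
#' \emph{absorption} spectrum (electron hops onto the neutral molecule)
#' is built from the NEUTRAL-basis Huang-Rhys table; the \emph{emission}
#' spectrum (electron hops off, the molecule relaxes from its charged
#' state) from the CHARGED-basis table.  For HCN this puts the dominant
#' emission band at the anionic C=N frequency (~1704 cm^-1), left-shifted
#' relative to the absorption band at the neutral frequency
#' (~2149 cm^-1).
#'
#' Inputs may be a \code{mode_table} of the right basis, or a pair of
#' \code{state_model}s from which the table is built via
#' [build_mode_table()].
#'
#' @param x a \code{mode_table}, or the neutral \code{state_model} (with
#'   \code{charged} supplied).
#' @param charged optional charged \code{state_model} when \code{x} is a
#'   state model.
#' @param upsilon_max,e0,sigma,grid_start,grid_stop,grid_step,mode,normalization
#'   spectral parameters; see [stick_spectrum()] and
#'   [convolve_spectrum()].  Defaults: progression sticks,
#'   \code{upsilon_max = 10}, \code{e0 = 0}, \code{sigma = 100} cm^-1,
#'   grid 0-4000 step 1, max-normalized.
#' @return A \code{convolved_spectrum} with the stick spectrum attached
#'   as \code{$sticks}.
#' @export
absorption_spectrum <- function(x, charged = NULL, upsilon_max = 10L,
                                e0 = 0, sigma = 100, grid_start = 0,
                                grid_stop = 4000, grid_step = 1,
                                mode = "progression",
                                normalization = "max1") {
  table <- .resolve_table(x, charged, "neutral")
  .et_spectrum(table, upsilon_max, e0, sigma, grid_start, grid_stop,
               grid_step, mode, normalization, "absorption")
}

#' @rdname absorption_spectrum
#' @export
emission_spectrum <- function(x, charged = NULL, upsilon_max = 10L,
                              e0 = 0, sigma = 100, grid_start = 0,
                              grid_stop = 4000, grid_step = 1,
                              mode = "progression",
                              normalization = "max1") {
  table <- .resolve_table(x, charged, "charged")
  .et_spectrum(table, upsilon_max, e0, sigma, grid_start, grid_stop,
               grid_step, mode, normalization, "emission")
}

.resolve_table <- function(x, charged, basis) {
  if (inherits(x, "mode_table")) {
    if (!identical(attr(x, "state_basis"), basis))
      .warnf("mode table has basis '%s' but the %s spectrum convention expects '%s'",
             attr(x, "state_basis"), if (basis == "neutral") "absorption" else "emission",
             basis)
    return(x)
  }
  if (inherits(x, "state_model") && inherits(charged, "state_model"))
    return(build_mode_table(x, charged, basis))
  .stopf("supply a mode_table, or a neutral and a charged state_model")
}

#' Inelastic electron tunneling intensities per mode
#'
#' Crude point-charge IETS model: the tunneling intensity of mode j is
#' \eqn{I_j = \sum_i q_i^2\,\Delta x_{i,j}^2}, where \eqn{q_i} is the
#' partial charge of atom i and \eqn{\Delta x_{i,j}} the Euclidean norm of
#' atom i's Cartesian displacement in mode j.  Invariant under a global
#' sign flip of the charges.  The source of the partial charges (Mulliken
#' or otherwise) is the caller's choice.
#'
#' @param charges per-atom partial charges, length n.
#' @param mode_cartesian_displacements 3n x n_v matrix of per-mode
#'   Cartesian displacement vectors (columns), ordering x1,y1,z1,...
#' @param frequencies_cm1 optional mode wavenumbers attached to the
#'   result.
#' @return An object of class \code{iets_spectrum}: data frame with
#'   columns \code{mode}, \code{omega_cm1} (may be NA), and
#'   \code{intensity}.
#' @export
iets_intensity <- function(charges, mode_cartesian_displacements,
                           frequencies_cm1 = NULL) {
  X <- as.matrix(mode_cartesian_displacements)
  n <- length(charges)
  if (nrow(X) != 3L * n)
    .stopf("displacement matrix has %d rows but %d charges imply %d",
           nrow(X), n, 3L * n)
  nv <- ncol(X)
  atom_of_row <- rep(seq_len(n), each = 3L)
  intensity <- vapply(seq_len(nv), function(j) {
    dx2 <- rowsum(X[, j]^2, atom_of_row)   # |Delta x_i,j|^2 per atom
    sum(charges^2 * dx2)
  }, numeric(1L))
  out <- data.frame(mode = seq_len(nv),
                    omega_cm1 = if (is.null(frequencies_cm1)) NA_real_
                                else frequencies_cm1,
                    intensity = intensity)
  class(out) <- c("iets_spectrum", "data.frame")
  out
}

#' Write a convolved spectrum to a two-column TSV
#'
#' Metadata (sigma, normalization) goes into \code{#} header lines;
#' [read_spectrum()] restores it.
#'
#' @param spectrum a \code{convolved_spectrum}; grid must be strictly
#'   increasing with no duplicate abscissae.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "convolved_spectrum"))
  if (length(spectrum$grid) == 0L) .stopf("empty spectrum grid")
  if (any(duplicated(spectrum$grid))) .stopf("duplicate grid abscissae")
  if (any(diff(spectrum$grid) <= 0)) .stopf("grid must be strictly increasing")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# sigma_cm1=%.17g", spectrum$sigma),
               sprintf("# normalization=%s", spectrum$normalization)), con)
  utils::write.table(
    data.frame(wavenumber_cm1 = spectrum$grid, intensity = spectrum$values),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a convolved spectrum written by [write_spectrum()]
#'
#' @param path TSV path.
#' @return A \code{convolved_spectrum}.
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) .stopf("spectrum file not found: %s", path)
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  getval <- function(key, default) {
    hit <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (length(hit)) sub(paste0("^# ", key, "="), "", hit[1L]) else default
  }
  df <- utils::read.delim(path, comment.char = "#")
  if (nrow(df) == 0L) .stopf("spectrum file has no rows: %s", path)
  structure(list(grid = df$wavenumber_cm1, values = df$intensity,
                 sigma = as.numeric(getval("sigma_cm1", NA)),
                 normalization = getval("normalization", "none")),
            class = "convolved_spectrum")
}
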