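#' Per-mode vibronic coupling table
#'
#' One row per normal mode of a chosen state basis: wavenumber
#' \code{omega_cm1}, Huang-Rhys factor \code{huang_rhys} (dimensionless
#' electron-vibrational coupling strength), per-mode reorganization energy
#' \code{lambda_eV}, and a free-text \code{assignment}.  When
#' \code{lambda_eV} is missing it is filled from \eqn{\lambda_j = \hbar
#' \omega_j \bar S_j}; when present it is consistency-checked against that
#' identity at half a unit of its last printed digit and a warning names
#' both values on mismatch (printed literature tables occasionally round
#' inconsistently).
#'
#' @param omega_cm1 wavenumbers, cm^-1, positive.
#' @param huang_rhys Huang-Rhys factors, >= 0.
#' @param lambda_eV optional per-mode reorganization energies, eV.
#' @param assignment optional character mode assignments.
#' @param state_basis \code{"neutral"} or \code{"charged"}: which state's
#'   normal modes the rows describe.
#' @return A \code{mode_table}: a data frame with the four columns above,
#'   rows sorted by ascending frequency, plus a \code{state_basis}
#'   attribute.
#' @export
mode_table <- function(omega_cm1, huang_rhys, lambda_eV = NULL,
                       assignment = NULL, state_basis = "neutral") {
  if (!state_basis %in% c("neutral", "charged"))
    .stopf("state_basis must be 'neutral' or 'charged'")
  m <- length(omega_cm1)
  if (m == 0L) .stopf("mode table has no rows")
  if (length(huang_rhys) != m)
    .stopf("huang_rhys: length %d does not match %d frequencies",
           length(huang_rhys), m)
  if (any(omega_cm1 <= 0)) .stopf("omega_cm1 must be positive")
  if (any(huang_rhys < 0)) .stopf("huang_rhys must be >= 0")
  recomputed <- mode_reorg_energy(omega_cm1, huang_rhys)
  if (is.null(lambda_eV)) {
    lambda_eV <- recomputed
  } else {
    if (length(lambda_eV) != m)
      .stopf("lambda_eV: length %d does not match %d frequencies",
             length(lambda_eV), m)
    fill <- is.na(lambda_eV)
    lambda_eV[fill] <- recomputed[fill]
    if (any(lambda_eV < 0)) .stopf("lambda_eV must be >= 0")
    check <- which(!fill)
    for (i in check) {
      tol <- 0.5 * .last_digit_unit(lambda_eV[i])
      if (abs(lambda_eV[i] - recomputed[i]) > tol + 1e-12)
        .warnf(paste0("mode %g cm^-1: given lambda = %g eV but ",
                      "hbar*omega*S = %.4g eV (beyond rounding tolerance %g)"),
               omega_cm1[i], lambda_eV[i], recomputed[i], tol)
    }
  }
  if (is.null(assignment)) assignment <- rep(NA_character_, m)
  ord <- order(omega_cm1)
  out <- data.frame(omega_cm1 = as.numeric(omega_cm1)[ord],
                    huang_rhys = as.numeric(huang_rhys)[ord],
                    lambda_eV = as.numeric(lambda_eV)[ord],
                    assignment = as.character(assignment)[ord],
                    stringsAsFactors = FALSE)
  attr(out, "state_basis") <- state_basis
  class(out) <- c("mode_table", "data.frame")
  out
}

# size of one unit in the last printed decimal of a value, e.g. 0.527 -> 1e-3.
# Values stored at full precision get a tight default.
.last_digit_unit <- function(x) {
  if (x == 0) return(1e-3)
  s <- sub("0+$", "", sub("^-", "", format(x, scientific = FALSE, digits = 15)))
  dot <- regexpr(".", s, fixed = TRUE)
  if (dot < 0) return(1)
  10^-(nchar(s) - dot)
}

#' @export
print.mode_table <- function(x, ...) {
  cat(sprintf("Vibronic mode table (%s basis), %d modes\n",
              attr(x, "state_basis"), nrow(x)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Read a per-mode (frequency, Huang-Rhys) table from TSV
#'
#' Expects tab-separated columns \code{omega_cm1}, \code{huang_rhys} and
#' optionally \code{lambda_eV} and \code{assignment}; lines starting with
#' \code{#} are ignored.  Missing \code{lambda_eV} entries are recomputed
#' from the Huang-Rhys identity; present ones are consistency-checked (see
#' [mode_table()]).
#'
#' @param path TSV path.
#' @param state_basis basis label for the resulting table.
#' @return A \code{mode_table}.
#' @export
read_mode_table <- function(path, state_basis = "neutral") {
  if (!file.exists(path)) .stopf("mode-table file not found: %s", path)
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) .stopf("mode-table file has no rows: %s", path)
  if (!all(c("omega_cm1", "huang_rhys") %in% names(df)))
    .stopf("mode-table file must have columns omega_cm1, huang_rhys")
  mode_table(df$omega_cm1, df$huang_rhys,
             lambda_eV = if ("lambda_eV" %in% names(df)) df$lambda_eV,
             assignment = if ("assignment" %in% names(df)) df$assignment,
             state_basis = state_basis)
}

#' Write a mode table to TSV
#'
#' @param table a \code{mode_table}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_mode_table <- function(table, path) {
  stopifnot(inherits(table, "mode_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# vibronic mode table, state_basis=%s",
                     attr(table, "state_basis")), con)
  utils::write.table(table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
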