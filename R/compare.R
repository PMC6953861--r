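# Spectral comparison: peak detection, windowed band overlap, and
# whole-spectrum cosine similarity.  These are the quantitative side of
# "do two odorants share a vibronic fingerprint": the band positions and
# shapes of the convolved emission spectra, not any perceptual claim.

#' Detect peaks in a convolved spectrum
#'
#' Local maxima with topographic prominence at least
#' \code{min_prominence} times the global maximum.  Prominence of a peak
#' is its height minus the higher of the two saddle minima separating it
#' from higher terrain (grid edges count as terrain ends).
#'
#' @param spectrum a \code{convolved_spectrum}.
#' @param min_prominence prominence threshold as a fraction of the global
#'   maximum (default 0.05).
#' @return A data frame of class \code{peak_list} with columns
#'   \code{position_cm1}, \code{height}, \code{prominence}, sorted by
#'   position.
#' @export
find_peaks <- function(spectrum, min_prominence = 0.05) {
  stopifnot(inherits(spectrum, "convolved_spectrum"))
  y <- spectrum$values
  x <- spectrum$grid
  n <- length(y)
  if (n == 0L) .stopf("empty spectrum")
  ymax <- max(y)
  empty <- data.frame(position_cm1 = numeric(), height = numeric(),
                      prominence = numeric())
  class(empty) <- c("peak_list", "data.frame")
  if (ymax <= 0) return(empty)
  # strict local maxima (plateaus take their first point)
  dy <- diff(y)
  cand <- which(c(dy, -1) < 0 & c(1, dy) > 0)
  if (!length(cand)) return(empty)
  prom <- vapply(cand, function(i) {
    h <- y[i]
    left <- if (i > 1L) y[seq_len(i - 1L)] else numeric()
    right <- if (i < n) y[(i + 1L):n] else numeric()
    key_saddle <- function(side) {
      if (!length(side)) return(min(h, 0))
      higher <- which(side > h)
      if (length(higher)) min(side[seq_len(min(higher))]) else min(side)
    }
    # left side scans toward the start, so reverse it
    h - max(key_saddle(rev(left)), key_saddle(right))
  }, numeric(1L))
  keep <- prom >= min_prominence * ymax
  out <- data.frame(position_cm1 = x[cand[keep]], height = y[cand[keep]],
                    prominence = prom[keep])
  out <- out[order(out$position_cm1), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_list", "data.frame")
  out
}

# linear interpolation of spectrum b onto grid of a, restricted to a window;
# returns list(grid, a, b)
.common_grid <- function(a, b, window = NULL) {
  lo <- max(min(a$grid), min(b$grid))
  hi <- min(max(a$grid), max(b$grid))
  if (!is.null(window)) {
    lo <- max(lo, window[1L]); hi <- min(hi, window[2L])
  }
  if (hi <= lo) .stopf("empty comparison window [%g, %g]", lo, hi)
  # coarser grid of the two, windowed
  ga <- a$grid[a$grid >= lo & a$grid <= hi]
  gb <- b$grid[b$grid >= lo & b$grid <= hi]
  g <- if (length(ga) <= length(gb)) ga else gb
  list(grid = g,
       a = stats::approx(a$grid, a$values, xout = g, rule = 2)$y,
       b = stats::approx(b$grid, b$values, xout = g, rule = 2)$y)
}

#' Windowed band overlap of two spectra
#'
#' Overlapping coefficient of the two curves inside a wavenumber window:
#' each is area-normalized over the window, then
#' \eqn{OVL = \int_{window} \min(\hat a, \hat b)\,d\tilde\nu}.  1 for
#' identical band shapes, 0 for disjoint ones; symmetric and invariant
#' under scaling either spectrum.  Grids are reconciled by linear
#' interpolation onto the coarser one.
#'
#' @param a,b \code{convolved_spectrum}s.
#' @param window length-2 numeric (lo, hi) in cm^-1; default the common
#'   grid range.
#' @return The overlap coefficient in [0, 1].
#' @export
band_overlap <- function(a, b, window = NULL) {
  cg <- .common_grid(a, b, window)
  ia <- .trapz(cg$grid, cg$a)
  ib <- .trapz(cg$grid, cg$b)
  if (ia <= 0 || ib <= 0) {
    .warnf("zero total intensity in the window; overlap defined as 0")
    return(0)
  }
  .trapz(cg$grid, pmin(cg$a / ia, cg$b / ib))
}

#' Cosine similarity of two spectra over their common grid
#'
#' \eqn{\sum a b / \sqrt{\sum a^2 \sum b^2}}; in [0, 1] for non-negative
#' spectra, 1 iff proportional.
#'
#' @param a,b \code{convolved_spectrum}s.
#' @return Cosine similarity.
#' @export
spectrum_similarity <- function(a, b) {
  cg <- .common_grid(a, b)
  na <- sqrt(sum(cg$a^2)); nb <- sqrt(sum(cg$b^2))
  if (na == 0 || nb == 0) .stopf("zero-norm spectrum")
  sum(cg$a * cg$b) / (na * nb)
}

#' Full comparison report between two spectra
#'
#' Combines the windowed overlap coefficient, the whole-grid cosine
#' similarity, and a peak-matching table pairing every peak of \code{a}
#' with its nearest peak of \code{b}.  Matches farther than
#' \code{match_tolerance} (default 250 cm^-1, about half the band width
#' attributed to biological tunneling detection) are reported as
#' unmatched.
#'
#' @param a,b \code{convolved_spectrum}s.
#' @param window comparison window (lo, hi) in cm^-1, or NULL for the
#'   full common range.
#' @param min_prominence peak threshold, see [find_peaks()].
#' @param match_tolerance maximum distance (cm^-1) for a peak pair to
#'   count as matched.
#' @return An object of class \code{overlap_report}: list with
#'   \code{window}, \code{overlap_coefficient}, \code{cosine_similarity},
#'   and \code{peak_matches} (data frame: position_a, position_b,
#'   distance, matched).
#' @export
compare_spectra <- function(a, b, window = NULL, min_prominence = 0.05,
                            match_tolerance = 250) {
  ovl <- band_overlap(a, b, window)
  cs <- spectrum_similarity(a, b)
  pa <- find_peaks(a, min_prominence)
  pb <- find_peaks(b, min_prominence)
  pm <- if (nrow(pa) && nrow(pb)) {
    nearest <- vapply(pa$position_cm1,
                      function(p) pb$position_cm1[which.min(abs(pb$position_cm1 - p))],
                      numeric(1L))
    data.frame(position_a = pa$position_cm1, position_b = nearest,
               distance = abs(pa$position_cm1 - nearest),
               matched = abs(pa$position_cm1 - nearest) <= match_tolerance)
  } else {
    data.frame(position_a = numeric(), position_b = numeric(),
               distance = numeric(), matched = logical())
  }
  structure(list(window = if (is.null(window))
                   c(max(min(a$grid), min(b$grid)),
                     min(max(a$grid), max(b$grid))) else window,
                 overlap_coefficient = ovl, cosine_similarity = cs,
                 peak_matches = pm),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("Spectral comparison over [%g, %g] cm^-1\n",
              x$window[1L], x$window[2L]))
  cat(sprintf("  overlap coefficient: %.3f\n", x$overlap_coefficient))
  cat(sprintf("  cosine similarity:   %.3f\n", x$cosine_similarity))
  if (nrow(x$peak_matches)) {
    cat(sprintf("  peak matches (%d/%d within tolerance):\n",
                sum(x$peak_matches$matched), nrow(x$peak_matches)))
    print.data.frame(x$peak_matches, row.names = FALSE)
  }
  invisible(x)
}
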