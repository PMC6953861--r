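# small shared helpers

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# trapezoid rule on an arbitrary monotone grid
.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

.is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x == round(x)
}

# log(n!) via lgamma, vectorized
.lfact <- function(n) lgamma(n + 1)

# orthonormality check for the columns of a matrix
.max_orthonormality_defect <- function(L) {
  g <- crossprod(L)
  max(abs(g - diag(ncol(L))))
}
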