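#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.25 -> 0.3 at one digit), the
#' convention used for reporting physical interval lengths in Mb. Base R's
#' `round()` rounds half to even, which disagrees on exact ties.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits.
#' @return Numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# recycle a per-chromosome parameter to length n with name checks
recycle_chrom <- function(x, n, what) {
  if (length(x) == 1L) x <- rep(x, n)
  if (length(x) != n) {
    stop(sprintf("`%s` must have length 1 or %d, got %d", what, n, length(x)),
         call. = FALSE)
  }
  x
}

#' Standard wheat chromosome labels
#'
#' @param n Number of chromosomes. Returns `1A ... 7D` when `n` is 21,
#'   otherwise `chr1 ... chrN`.
#' @return Character vector of chromosome names.
#' @export
chromosome_names <- function(n) {
  if (n == 21L) paste0(rep(1:7, each = 3), rep(c("A", "B", "D"), 7))
  else paste0("chr", seq_len(n))
}

# empirical re-scaling of a draw to an exact variance (and zero mean);
# keeps realized simulation variance components on target at small n
scale_to_var <- function(x, v) {
  if (v <= 0 || length(x) < 2L) return(rep(0, length(x)))
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s == 0) return(rep(0, length(x)))
  x / s * sqrt(v)
}
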