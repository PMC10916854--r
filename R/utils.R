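#' Derive a reproducible per-well RNG seed
#'
#' Each well gets its own RNG stream keyed by (plate, row, column, global
#' seed), so any single well can be regenerated without replaying the whole
#' screen. The derivation is a small multiplicative hash folded into the
#' 32-bit signed integer range accepted by [set.seed()].
#'
#' @param seed Global integer seed.
#' @param plate Plate index (1-based).
#' @param row Well row (1-16).
#' @param col Well column (1-24).
#' @return A single integer seed.
#' @export
well_seed <- function(seed, plate, row, col) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  # fold into [0, 2^31 - 2]; coefficients are arbitrary odd primes
  h <- (as.double(seed) %% 2147483647) * 7919 +
    as.double(plate) * 104729 + as.double(row) * 1299709 + as.double(col) * 15485863
  as.integer(h %% 2147483646) + 1L
}

#' Round half away from zero
#'
#' Base R `round()` rounds half to even; screen summary percentages follow the
#' conventional half-up rule so that e.g. 86.35 prints as 86.4.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# robust spread: MAD scaled by the normal-consistency constant
robust_sd <- function(x) 1.4826 * stats::mad(x, constant = 1, na.rm = TRUE)

# quiet logger used for non-fatal conditions the contracts ask to record
cs_log <- function(...) {
  if (isTRUE(getOption("cargoscreen.verbose", FALSE))) message(sprintf(...))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
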