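# Shared helpers.

#' Round half away from zero
#'
#' Percentages in reports are rounded half away from zero (so 0.125 at two
#' decimals becomes 0.13), matching the usual convention for printed
#' sequencing statistics rather than base R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Reverse complement of a DNA string
#'
#' @param x Character vector of sequences over A/C/G/T/N.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Fast substring of a reference chromosome (plain character scalar).
ref_sub <- function(refseq, start, end) {
  if (end < start) return("")
  substr(refseq, start, end)
}

# stopifnot with a formatted message
fail_if <- function(cond, fmt, ...) {
  if (cond) stop(sprintf(fmt, ...), call. = FALSE)
}
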