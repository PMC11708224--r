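#' Round half away from zero at a fixed number of decimals
#'
#' Printed genome-report percentages use conventional half-up rounding,
#' not the IEEE round-half-even that [base::round()] applies.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences over {A,C,G,T,N}.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  out
}

#' Random DNA sequence
#'
#' Uniform i.i.d. bases; uses the current RNG state.
#'
#' @param n sequence length in bp.
#' @return a single DNA string of length `n`.
#' @keywords internal
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# stop() with sprintf formatting, no call in the condition
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
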