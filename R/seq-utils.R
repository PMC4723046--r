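DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a nucleotide string
#'
#' Complements A/C/G/T (case-insensitive input is upper-cased first), keeps
#' `N` and the gap character `-`, and reverses the sequence.
#'
#' @param x single nucleotide string.
#' @return reverse-complemented string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  cpp_revcomp(toupper(x))
}

#' GC content of a nucleotide sequence
#'
#' Fraction (G + C) / (A + C + G + T); ambiguous bases and gaps are excluded
#' from the denominator.  Rounded to 4 decimals.
#'
#' @param x nucleotide string.
#' @return GC fraction in \[0, 1\], 4 decimals.
#' @export
gc_content <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, nchar(x) > 0L)
  counts <- base_counts(toupper(x))
  denom <- sum(counts)
  if (denom == 0L) stop("sequence contains no unambiguous A/C/G/T bases")
  round((counts[["G"]] + counts[["C"]]) / denom, 4L)
}

base_counts <- function(x) {
  r <- charToRaw(x)
  vapply(DNA_BASES, function(b) sum(r == charToRaw(b)), integer(1))
}

#' Random i.i.d. nucleotide sequence at a target GC content
#'
#' @param n length in bp.
#' @param gc expected GC fraction.
#' @return nucleotide string of length `n`.
#' @export
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Rotate a circular sequence
#'
#' @param x sequence string.
#' @param offset 0-based position that becomes the new origin.
#' @return rotated string of the same length.
#' @export
rotate_seq <- function(x, offset) {
  n <- nchar(x)
  offset <- ((offset %% n) + n) %% n
  if (offset == 0) return(x)
  paste0(substr(x, offset + 1L, n), substr(x, 1L, offset))
}

# Extract [start, end) from a sequence, wrapping past the end when circular.
subseq_circ <- function(x, start, end, circular = TRUE) {
  n <- nchar(x)
  stopifnot(start >= 0, end >= start)
  if (end <= n) return(substr(x, start + 1L, end))
  if (!circular) stop("interval extends past the end of a linear sequence")
  paste0(substr(x, start + 1L, n), substr(x, 1L, end - n))
}

# split into single characters
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

phred_char <- function(q) intToUtf8(q + 33L, multiple = FALSE)
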