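# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC bitmask encoding: A=1, C=2, G=4, T=8. Used by the degenerate-trace
# superposition and decoder, where positions carry sets of bases.
IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L
)
BITS_IUPAC <- {
  x <- character(15L)
  x[IUPAC_BITS] <- names(IUPAC_BITS)
  x
}

base_to_bits <- function(chars) {
  b <- IUPAC_BITS[chars]
  if (anyNA(b)) stop("non-IUPAC character in sequence: ",
                     paste(unique(chars[is.na(b)]), collapse = ","))
  unname(b)
}

bits_to_base <- function(bits) BITS_IUPAC[bits]

str_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

#' Round half away from zero to a fixed number of decimals
#'
#' Base R's `round()` rounds half to even; printed tables in this field
#' conventionally round half up (e.g. 24.65 -> 24.7).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  # guard against binary representation error (24.65 * 10 = 246.4999...)
  eps <- sqrt(.Machine$double.eps) * pmax(1, abs(x) * p)
  sign(x) * floor(abs(x) * p + 0.5 + eps) / p
}

pct <- function(n, d, digits = 1) {
  if (d == 0) return(0)
  round_half_up(100 * n / d, digits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
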