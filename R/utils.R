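# Internal helpers shared across modules.

# Round half away from zero (presentation rounding for integer percent shares;
# base round() rounds half to even).
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

# Truncate to one decimal, guarding against 8.2999999... artefacts.
trunc1 <- function(x) floor(x * 10 + 1e-9) / 10

#' Normalize chromosome labels to integer autosome indices
#'
#' Maps the common equine labellings (`"3"`, `"chr3"`, `"ECA3"`) to the
#' integer `3`. The sex chromosomes and mitochondrion follow the PLINK horse
#' convention (`X` = 32, `Y` = 33, `XY` = 34, `MT` = 35) so that the autosome
#' filter (1..31) can drop them. Unrecognized labels become `NA`.
#'
#' @param x character or numeric vector of chromosome labels.
#' @return integer vector, `NA` where the label is not recognized.
#' @export
normalize_chrom <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x <- sub("^CHR", "", x)
  x <- sub("^ECA", "", x)
  out <- suppressWarnings(as.integer(x))
  special <- c(X = 32L, Y = 33L, XY = 34L, MT = 35L, M = 35L)
  miss <- is.na(out) & x %in% names(special)
  out[miss] <- special[x[miss]]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
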