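#' @useDynLib ampkit, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# IUPAC nucleotide ambiguity codes as base bitmasks: A=1, C=2, G=4, T=8.
# U is folded into T by normalization before any lookup.
.iupac_bits <- c(
  A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
  R = 5L,  # A/G
  Y = 10L, # C/T
  S = 6L,  # C/G
  W = 9L,  # A/T
  K = 12L, # G/T
  M = 3L,  # A/C
  B = 14L, # C/G/T
  D = 13L, # A/G/T
  H = 11L, # A/C/T
  V = 7L,  # A/C/G
  N = 15L
)

.iupac_complement <- c(
  A = "T", C = "G", G = "C", T = "A", U = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N", "-" = "-", "." = "."
)

#' Normalize a nucleotide string
#'
#' Uppercases and maps U to T. Idempotent; gap characters (`-`, `.`) pass
#' through untouched.
#'
#' @param x character vector of sequences.
#' @return character vector of normalized sequences.
#' @export
normalize_bases <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

#' Validate IUPAC nucleotide strings
#'
#' @param x character vector (normalized).
#' @param allow_gaps also accept `-` and `.`.
#' @return invisibly TRUE; errors on the first invalid character.
#' @keywords internal
check_iupac <- function(x, allow_gaps = FALSE) {
  ok <- names(.iupac_bits)
  if (allow_gaps) ok <- c(ok, "-", ".")
  bad <- setdiff(unique(unlist(strsplit(x, "", fixed = TRUE))), ok)
  if (length(bad) > 0) {
    stop("invalid IUPAC character(s): ", paste(bad, collapse = " "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Reverse complement
#'
#' IUPAC-aware reverse complement; gaps are preserved.
#'
#' @param x character vector of (normalized) nucleotide strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  x <- normalize_bases(x)
  vapply(strsplit(x, "", fixed = TRUE), function(ch) {
    comp <- .iupac_complement[ch]
    if (anyNA(comp)) {
      stop("cannot reverse-complement character(s): ",
           paste(unique(ch[is.na(comp)]), collapse = " "), call. = FALSE)
    }
    paste(rev(comp), collapse = "")
  }, character(1))
}

# bitmask vector for a string; unknown characters get 0 (never match by set)
iupac_bits_of <- function(s) {
  b <- .iupac_bits[strsplit(s, "", fixed = TRUE)[[1]]]
  b[is.na(b)] <- 0L
  unname(b)
}

#' Expand a degenerate IUPAC oligo to one concrete realization
#'
#' Each ambiguity code is replaced by one of the bases it encodes, chosen
#' uniformly with the current RNG (used by the read simulator, where every
#' amplicon carries a concrete synthetic oligo).
#'
#' @param x single IUPAC string.
#' @return concrete string over ACGT.
#' @keywords internal
sample_iupac_expansion <- function(x) {
  bases <- c("A", "C", "G", "T")
  bits <- iupac_bits_of(x)
  if (any(bits == 0L)) stop("invalid IUPAC character in oligo", call. = FALSE)
  paste(vapply(bits, function(b) {
    opts <- bases[bitwAnd(b, c(1L, 2L, 4L, 8L)) > 0L]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1)), collapse = "")
}
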