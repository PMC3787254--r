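#' Global (Needleman-Wunsch) pairwise alignment
#'
#' Optimal global alignment under a fixed linear scoring scheme:
#' match +1, mismatch -1, gap -2. The traceback is deterministic
#' (diagonal preferred, then gap-in-read) and gap columns are afterwards
#' slid to the 3'-most equivalent position of their homopolymer run, so
#' that indel records have a well-defined homopolymer context. Sliding a
#' gap right is score-neutral in an optimal alignment, so optimality is
#' preserved.
#'
#' @param read,ref nonempty (normalized) sequences; `read` is the query
#'   whose errors are being typed, `ref` the reference.
#' @return list of class `pairwise_aln`: `score`, `read_aln`, `ref_aln`
#'   (equal-length gapped strings).
#' @export
global_align <- function(read, ref) {
  if (!nzchar(read) || !nzchar(ref)) {
    stop("global alignment of an empty sequence", call. = FALSE)
  }
  raw <- cpp_nw_align(read, ref)
  canon <- canonicalize_gaps(strsplit(raw$aligned_a, "", fixed = TRUE)[[1]],
                             strsplit(raw$aligned_b, "", fixed = TRUE)[[1]])
  structure(list(score = raw$score,
                 read_aln = paste(canon$a, collapse = ""),
                 ref_aln = paste(canon$b, collapse = "")),
            class = "pairwise_aln")
}

# Slide gap columns 3'-wards whenever the swap is sequence-preserving:
# a gap in `a` at column c moves right past column c+1 when a[c+1] equals
# b[c] (and symmetrically for gaps in `b`). In an optimal alignment each
# such swap leaves the score unchanged.
canonicalize_gaps <- function(a, b) {
  L <- length(a)
  repeat {
    changed <- FALSE
    for (c in seq_len(L - 1L)) {
      if (a[c] == "-" && a[c + 1L] != "-" && b[c + 1L] != "-" &&
          a[c + 1L] == b[c]) {
        a[c] <- a[c + 1L]; a[c + 1L] <- "-"
        changed <- TRUE
      } else if (b[c] == "-" && b[c + 1L] != "-" && a[c + 1L] != "-" &&
                 b[c + 1L] == a[c]) {
        b[c] <- b[c + 1L]; b[c + 1L] <- "-"
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  list(a = a, b = b)
}

#' Align a read against every reference and keep the best
#'
#' The reference producing the highest global alignment score identifies
#' the source organism; ties go to the first-listed reference and are
#' flagged ambiguous.
#'
#' @param read sequence string.
#' @param refs named character vector of reference sequences (trimmed to
#'   the amplicon region the reads cover).
#' @return the winning `pairwise_aln` with `ref_id` and `ambiguous`
#'   fields added.
#' @export
assign_best_reference <- function(read, refs) {
  if (length(refs) == 0) stop("empty reference set", call. = FALSE)
  if (is.null(names(refs)) || any(!nzchar(names(refs)))) {
    stop("references must be named", call. = FALSE)
  }
  best <- NULL
  ambiguous <- FALSE
  for (k in seq_along(refs)) {
    al <- global_align(read, refs[[k]])
    if (is.null(best)) {
      best <- al
      best$ref_id <- names(refs)[k]
    } else if (al$score > best$score) {
      best <- al
      best$ref_id <- names(refs)[k]
      ambiguous <- FALSE
    } else if (al$score == best$score) {
      ambiguous <- TRUE
    }
  }
  best$ambiguous <- ambiguous
  best
}
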