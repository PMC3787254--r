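#' Masked multiple sequence alignment
#'
#' An aligned FASTA file carrying a `#=GC_RF` meta row that marks the
#' model (match) columns of a profile alignment. Columns where the mask
#' holds a gap character (`.` or `-`) are insert states and are excluded
#' from all sequence comparisons; the remaining columns are comparable
#' across any two files aligned to the same profile.
#'
#' @param ids record ids.
#' @param seqs aligned sequence strings (residues plus `-`/`.` gaps), all
#'   of equal length.
#' @param mask the `#=GC_RF` string, same length as the records.
#' @return an object of class `masked_aln`.
#' @export
masked_alignment <- function(ids, seqs, mask) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs)) stop("ids/seqs length mismatch",
                                        call. = FALSE)
  if (anyDuplicated(ids)) {
    stop("duplicate alignment id: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  w <- nchar(mask)
  bad <- which(nchar(seqs) != w)
  if (length(bad) > 0) {
    stop("record '", ids[bad[1]], "' length ", nchar(seqs[bad[1]]),
         " != mask length ", w, call. = FALSE)
  }
  structure(list(ids = ids, seqs = seqs, mask = mask), class = "masked_aln")
}

#' @export
print.masked_aln <- function(x, ...) {
  cat(sprintf("<masked_aln> %d record(s), %d column(s), %d comparable\n",
              length(x$ids), nchar(x$mask), length(comparable_columns(x))))
  invisible(x)
}

MASK_ID <- "#=GC_RF"

#' Load a masked alignment from aligned FASTA
#'
#' The file must contain a `#=GC_RF` record; any record whose id starts
#' with `#=GC` is treated as metadata, never as a sequence. When several
#' paths are given the files are merged, which is valid only if their
#' masks are identical (alignments produced from the same profile model).
#'
#' @param paths one or more aligned FASTA files.
#' @return a [masked_alignment()] object.
#' @export
load_masked_alignment <- function(paths) {
  parts <- lapply(paths, function(path) {
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    rec <- parse_fasta(sub("\r$", "", readLines(path, warn = FALSE)))
    meta <- startsWith(rec$id, "#=GC")
    mask_i <- which(rec$id == MASK_ID)
    if (length(mask_i) != 1) {
      stop("alignment file '", path, "' lacks the ", MASK_ID,
           " mask row; it must be present in all alignment files",
           call. = FALSE)
    }
    masked_alignment(rec$id[!meta], rec$seq[!meta], rec$seq[mask_i])
  })
  Reduce(merge_masked_alignments, parts)
}

#' Merge two masked alignments aligned to the same profile
#'
#' @param a,b `masked_aln` objects with identical masks.
#' @return the concatenated `masked_aln`.
#' @export
merge_masked_alignments <- function(a, b) {
  if (!identical(a$mask, b$mask)) {
    stop("cannot merge alignments with different #=GC_RF masks",
         call. = FALSE)
  }
  masked_alignment(c(a$ids, b$ids), c(a$seqs, b$seqs), a$mask)
}

#' Comparable (non-insert) column positions of a masked alignment
#'
#' @param maln a `masked_aln`.
#' @return integer vector of column indices where the mask is not a gap.
#' @export
comparable_columns <- function(maln) {
  ch <- strsplit(maln$mask, "", fixed = TRUE)[[1]]
  which(!(ch %in% c(".", "-")))
}

#' Write a masked alignment to aligned FASTA
#'
#' @param maln a `masked_aln`.
#' @param path output file.
#' @return invisibly `path`.
#' @export
write_masked_alignment <- function(maln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(maln$ids)) {
    writeLines(c(paste0(">", maln$ids[i]), maln$seqs[i]), con)
  }
  writeLines(c(paste0(">", MASK_ID), maln$mask), con)
  invisible(path)
}

#' Build a degenerate masked alignment from equal-length sequences
#'
#' Pre-aligned or untrimmed equal-length sequences (e.g. error-free
#' simulated amplicons) become a gap-free alignment whose every column is
#' comparable. This stands in for an external profile aligner in
#' desk-scale pipelines; it refuses ragged input.
#'
#' @param reads an [amp_reads] object with equal-length sequences.
#' @return a `masked_aln`.
#' @export
as_masked_alignment <- function(reads) {
  w <- unique(nchar(reads$bases))
  if (length(w) != 1) {
    stop("sequences are not of equal length; align them with a profile ",
         "aligner first", call. = FALSE)
  }
  masked_alignment(reads$id, reads$bases, strrep("x", w))
}
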