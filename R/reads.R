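#' Sequence read container
#'
#' A plain columnar container for sequence records with optional per-base
#' Phred quality scores and sample provenance. Bases are normalized
#' (uppercase, U mapped to T) on construction.
#'
#' @param id character vector of record ids (nonempty, unique).
#' @param bases character vector of sequences.
#' @param quals `NULL`, or a list of integer vectors, one per read, each the
#'   same length as the corresponding sequence.
#' @param sample character vector of sample labels (recycled), or `NA`.
#' @return an object of class `amp_reads`.
#' @export
amp_reads <- function(id, bases, quals = NULL, sample = NA_character_) {
  id <- as.character(id)
  bases <- normalize_bases(as.character(bases))
  if (length(id) != length(bases)) {
    stop("id and bases must have the same length", call. = FALSE)
  }
  if (any(!nzchar(id))) stop("empty read id", call. = FALSE)
  if (anyDuplicated(id)) {
    stop("duplicate read id(s): ",
         paste(unique(id[duplicated(id)]), collapse = " "), call. = FALSE)
  }
  if (!is.null(quals)) {
    if (!is.list(quals) || length(quals) != length(id)) {
      stop("quals must be a list with one entry per read", call. = FALSE)
    }
    quals <- lapply(quals, function(q) as.integer(q))
    bad <- which(lengths(quals) != nchar(bases))
    if (length(bad) > 0) {
      stop("sequence/quality length mismatch for read '", id[bad[1]], "'",
           call. = FALSE)
    }
  }
  sample <- rep_len(as.character(sample), length(id))
  structure(list(id = id, bases = bases, quals = quals, sample = sample),
            class = "amp_reads")
}

#' @export
length.amp_reads <- function(x) length(x$id)

#' @export
`[.amp_reads` <- function(x, i) {
  amp_reads(x$id[i], x$bases[i],
            if (!is.null(x$quals)) x$quals[i] else NULL,
            x$sample[i])
}

#' @export
print.amp_reads <- function(x, ...) {
  cat(sprintf("<amp_reads> %d read(s)%s\n", length(x),
              if (is.null(x$quals)) "" else " with quality scores"))
  n <- min(length(x), 5L)
  for (i in seq_len(n)) {
    b <- x$bases[i]
    cat(sprintf("  %s  %s%s  (%d bp)\n", x$id[i],
                substr(b, 1, 40), if (nchar(b) > 40) "..." else "",
                nchar(b)))
  }
  if (length(x) > n) cat("  ...\n")
  invisible(x)
}

#' @export
c.amp_reads <- function(...) {
  parts <- list(...)
  quals <- NULL
  if (all(vapply(parts, function(p) !is.null(p$quals), logical(1)))) {
    quals <- do.call(c, lapply(parts, `[[`, "quals"))
  }
  amp_reads(unlist(lapply(parts, `[[`, "id")),
            unlist(lapply(parts, `[[`, "bases")),
            quals,
            unlist(lapply(parts, `[[`, "sample")))
}

has_quals <- function(x) !is.null(x$quals)
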