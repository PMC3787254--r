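#' Read sequence files
#'
#' Loads FASTA (optionally with a parallel QUAL file) or FASTQ (Sanger
#' Phred+33) into an [amp_reads] container. Bases are normalized to
#' uppercase with U mapped to T. Both `\n` and `\r\n` line endings are
#' accepted; multi-line FASTA records are supported, FASTQ records must be
#' the standard four lines.
#'
#' @param path input file.
#' @param format `"auto"` (by extension / leading character), `"fasta"` or
#'   `"fastq"`.
#' @param qual_path optional QUAL file accompanying a FASTA input; every
#'   FASTA id must have a QUAL entry of matching length.
#' @param sample optional sample label attached to every read (defaults to
#'   the file name without extension).
#' @return an [amp_reads] object.
#' @export
load_reads <- function(path, format = c("auto", "fasta", "fastq"),
                       qual_path = NULL, sample = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(sample)) {
    sample <- tools::file_path_sans_ext(basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  if (format == "auto") {
    first <- lines[nzchar(lines)][1]
    format <- if (!is.na(first) && startsWith(first, "@")) "fastq" else "fasta"
  }
  if (format == "fastq") {
    if (!is.null(qual_path)) {
      stop("QUAL files accompany FASTA input only", call. = FALSE)
    }
    return(parse_fastq(lines, sample))
  }
  rec <- parse_fasta(lines)
  quals <- NULL
  if (!is.null(qual_path)) {
    qtab <- parse_qual(qual_path)
    missing <- setdiff(rec$id, names(qtab))
    if (length(missing) > 0) {
      stop("no QUAL entry for read '", missing[1], "'", call. = FALSE)
    }
    quals <- unname(qtab[rec$id])
    bad <- which(lengths(quals) != nchar(rec$seq))
    if (length(bad) > 0) {
      stop("sequence/quality length mismatch for read '", rec$id[bad[1]], "'",
           call. = FALSE)
    }
  }
  amp_reads(rec$id, rec$seq, quals, sample)
}

# shared FASTA block parser; returns list(id, desc, seq)
parse_fasta <- function(lines) {
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (length(lines) == 0 || !hdr[1]) {
    stop("malformed FASTA: expected '>' header", call. = FALSE)
  }
  grp <- cumsum(hdr)
  heads <- sub("^>", "", lines[hdr])
  id <- sub("\\s.*$", "", heads)
  desc <- ifelse(grepl("\\s", heads), sub("^\\S+\\s+", "", heads), "")
  if (any(!nzchar(id))) stop("malformed FASTA: empty record id", call. = FALSE)
  if (anyDuplicated(id)) {
    stop("duplicate record id: ", id[duplicated(id)][1], call. = FALSE)
  }
  seq <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1),
                collapse = "")
  # records with no sequence lines need empty strings in order
  out <- character(length(id))
  names(out) <- as.character(seq_along(id))
  out[names(seq)] <- seq
  list(id = id, desc = desc, seq = unname(out))
}

parse_fastq <- function(lines, sample) {
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 4 != 0) {
    stop("malformed FASTQ: number of lines is not a multiple of 4",
         call. = FALSE)
  }
  idx <- seq(1, length(lines), by = 4)
  if (!all(startsWith(lines[idx], "@"))) {
    stop("malformed FASTQ: record header missing '@'", call. = FALSE)
  }
  id <- sub("\\s.*$", "", sub("^@", "", lines[idx]))
  seq <- lines[idx + 1]
  qstr <- lines[idx + 3]
  bad <- which(nchar(seq) != nchar(qstr))
  if (length(bad) > 0) {
    stop("sequence/quality length mismatch for read '", id[bad[1]], "'",
         call. = FALSE)
  }
  quals <- lapply(qstr, function(s) as.integer(utf8ToInt(s)) - 33L)
  amp_reads(id, seq, quals, sample)
}

parse_qual <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  rec <- parse_fasta(lines)
  q <- lapply(rec$seq, function(s) {
    s <- trimws(s)
    if (!nzchar(s)) return(integer(0))
    as.integer(strsplit(gsub("\\s+", " ", s), " ", fixed = TRUE)[[1]])
  })
  names(q) <- rec$id
  q
}

#' Write reads to FASTA/FASTQ (+QUAL)
#'
#' @param reads an [amp_reads] object.
#' @param path output file.
#' @param format `"fasta"` or `"fastq"`; FASTQ requires quality scores.
#' @param qual_path optional QUAL output path (FASTA only).
#' @param width line width for FASTA sequence wrapping (0 = no wrap).
#' @return invisibly `path`.
#' @export
write_reads <- function(reads, path, format = c("fasta", "fastq"),
                        qual_path = NULL, width = 0L) {
  format <- match.arg(format)
  if (format == "fastq") {
    if (!has_quals(reads)) stop("FASTQ output requires qualities", call. = FALSE)
    qstr <- vapply(reads$quals, function(q) intToUtf8(q + 33L), character(1))
    out <- as.vector(rbind(paste0("@", reads$id), reads$bases, "+", qstr))
    writeLines(out, path, sep = "\n")
    return(invisible(path))
  }
  wrap <- function(s) {
    if (width <= 0L || nchar(s) <= width) return(s)
    substring(s, seq(1, nchar(s), by = width),
              pmin(nchar(s), seq(width, nchar(s) + width - 1, by = width)))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(reads$id)) {
    writeLines(c(paste0(">", reads$id[i]), wrap(reads$bases[i])), con)
  }
  if (!is.null(qual_path)) {
    if (!has_quals(reads)) stop("no qualities to write", call. = FALSE)
    qcon <- file(qual_path, "w")
    on.exit(close(qcon), add = TRUE)
    for (i in seq_along(reads$id)) {
      writeLines(c(paste0(">", reads$id[i]),
                   paste(reads$quals[[i]], collapse = " ")), qcon)
    }
  }
  invisible(path)
}

#' Parse a tag (MID) table
#'
#' Tab-delimited `tag<TAB>sample` pairs. Tags are normalized to uppercase
#' and must be unique and prefix-free (no tag may be a prefix of another),
#' which makes 5' demultiplexing unambiguous.
#'
#' @param path tag file.
#' @return a `tag_table`: data.frame with columns `tag`, `sample`.
#' @export
parse_tag_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop("tag file must have exactly two tab-separated columns (line ",
         which(lengths(parts) != 2L)[1], ")", call. = FALSE)
  }
  tag <- normalize_bases(vapply(parts, `[`, character(1), 1L))
  sample <- trimws(vapply(parts, `[`, character(1), 2L))
  check_iupac(tag)
  if (anyDuplicated(tag)) {
    stop("duplicate tag: ", tag[duplicated(tag)][1], call. = FALSE)
  }
  if (any(!nzchar(sample))) {
    stop("blank sample id in tag file (line ", which(!nzchar(sample))[1], ")",
         call. = FALSE)
  }
  for (i in seq_along(tag)) {
    pre <- tag[-i][startsWith(tag[-i], tag[i])]
    if (length(pre) > 0) {
      stop("tag '", tag[i], "' is a prefix of tag '", pre[1], "'",
           call. = FALSE)
    }
  }
  structure(data.frame(tag = tag, sample = sample,
                       stringsAsFactors = FALSE),
            class = c("tag_table", "data.frame"))
}
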