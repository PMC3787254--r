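#' Tabulate substitution and indel errors from a pairwise alignment
#'
#' Walks the (gap-canonicalized) alignment columns and emits one record
#' per error column. Substitution records carry the 1-based alignment
#' position and the expected (reference) and observed (read) bases.
#' Indel records carry the indel base, the expected and observed
#' homopolymer run lengths (maximal runs of the indel base in the
#' ungapped reference and read at that locus), the 1-based positions in
#' the read and the reference (non-gap characters consumed), and -- for
#' insertions when quality is available -- the Q score of the extra base.
#'
#' @param aln a `pairwise_aln` from [global_align()] or
#'   [assign_best_reference()].
#' @param read_id,ref_id record ids for the output tables.
#' @param quals optional integer qualities of the (unaligned) read.
#' @return list with data.frames `substitutions` and `indels`.
#' @export
tabulate_errors <- function(aln, read_id = "read", ref_id = NULL,
                            quals = NULL) {
  if (is.null(ref_id)) {
    ref_id <- if (!is.null(aln$ref_id)) aln$ref_id else "ref"
  }
  a <- strsplit(aln$read_aln, "", fixed = TRUE)[[1]]
  b <- strsplit(aln$ref_aln, "", fixed = TRUE)[[1]]
  read_seq <- a[a != "-"]
  ref_seq <- b[b != "-"]
  run_len <- function(seq, pos, base) {
    if (pos < 1 || pos > length(seq) || seq[pos] != base) return(0L)
    lo <- pos
    while (lo > 1L && seq[lo - 1L] == base) lo <- lo - 1L
    hi <- pos
    while (hi < length(seq) && seq[hi + 1L] == base) hi <- hi + 1L
    hi - lo + 1L
  }
  subs <- list()
  indels <- list()
  rp <- 0L  # read bases consumed
  fp <- 0L  # ref bases consumed
  for (c in seq_along(a)) {
    ag <- a[c] == "-"
    bg <- b[c] == "-"
    if (!ag) rp <- rp + 1L
    if (!bg) fp <- fp + 1L
    if (!ag && !bg) {
      if (a[c] != b[c]) {
        subs[[length(subs) + 1L]] <- data.frame(
          read_id = read_id, ref_id = ref_id, aln_pos = c,
          expected = b[c], observed = a[c], stringsAsFactors = FALSE)
      }
    } else if (bg) {  # gap in reference: insertion in the read
      base <- a[c]
      obs <- run_len(read_seq, rp, base)
      exp_len <- run_len(ref_seq, fp, base)
      if (exp_len == 0L) exp_len <- run_len(ref_seq, fp + 1L, base)
      indels[[length(indels) + 1L]] <- data.frame(
        read_id = read_id, ref_id = ref_id, type = "insertion",
        aln_pos = c, expected_len = exp_len, observed_len = obs,
        base = base, read_pos = rp, ref_pos = fp,
        qual = if (!is.null(quals) && rp <= length(quals))
          as.integer(quals[rp]) else NA_integer_,
        stringsAsFactors = FALSE)
    } else {  # gap in read: deletion
      base <- b[c]
      exp_len <- run_len(ref_seq, fp, base)
      obs <- run_len(read_seq, rp, base)
      if (obs == 0L) obs <- run_len(read_seq, rp + 1L, base)
      indels[[length(indels) + 1L]] <- data.frame(
        read_id = read_id, ref_id = ref_id, type = "deletion",
        aln_pos = c, expected_len = exp_len, observed_len = obs,
        base = base, read_pos = rp, ref_pos = fp, qual = NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  empty_subs <- data.frame(read_id = character(0), ref_id = character(0),
                           aln_pos = integer(0), expected = character(0),
                           observed = character(0), stringsAsFactors = FALSE)
  empty_ind <- data.frame(read_id = character(0), ref_id = character(0),
                          type = character(0), aln_pos = integer(0),
                          expected_len = integer(0), observed_len = integer(0),
                          base = character(0), read_pos = integer(0),
                          ref_pos = integer(0), qual = integer(0),
                          stringsAsFactors = FALSE)
  list(substitutions = if (length(subs)) do.call(rbind, subs) else empty_subs,
       indels = if (length(indels)) do.call(rbind, indels) else empty_ind)
}

#' Profile sequencing errors against a defined (mock) community
#'
#' Globally aligns every read against every reference, assigns each read
#' to its best-scoring reference, and tabulates substitution and indel
#' errors with homopolymer context. Duplicate read strings are aligned
#' once and the records replicated.
#'
#' @param reads an [amp_reads] object (qualities used when present).
#' @param refs named character vector of reference sequences covering the
#'   identical region as the reads.
#' @return an `error_analysis` object: `per_read` data.frame (id, ref,
#'   score, ref_bases aligned, error counts, rq), `substitutions`,
#'   `indels`, and `alignments` (list of `pairwise_aln`).
#' @export
error_analysis <- function(reads, refs) {
  if (length(refs) == 0) stop("empty reference set", call. = FALSE)
  refs <- normalize_bases(refs)
  drp <- dereplicate(reads)
  uniq <- drp$unique
  ualn <- vector("list", length(uniq))
  names(ualn) <- uniq$id
  for (i in seq_len(length(uniq))) {
    ualn[[i]] <- assign_best_reference(uniq$bases[i], refs)
  }
  rep_of <- rep(vapply(drp$id_map, `[`, character(1), 1L),
                lengths(drp$id_map))
  names(rep_of) <- unlist(drp$id_map, use.names = FALSE)
  per <- vector("list", length(reads))
  subs <- list()
  inds <- list()
  alns <- vector("list", length(reads))
  names(alns) <- reads$id
  for (i in seq_len(length(reads))) {
    id <- reads$id[i]
    al <- ualn[[rep_of[[id]]]]
    alns[[id]] <- al
    q <- if (has_quals(reads)) reads$quals[[i]] else NULL
    tab <- tabulate_errors(al, read_id = id, quals = q)
    subs[[i]] <- tab$substitutions
    inds[[i]] <- tab$indels
    per[[i]] <- data.frame(
      id = id, ref_id = al$ref_id, score = al$score,
      ambiguous = al$ambiguous,
      aln_len = nchar(al$read_aln),
      ref_bases = nchar(gsub("-", "", al$ref_aln, fixed = TRUE)),
      n_sub = nrow(tab$substitutions),
      n_ins = sum(tab$indels$type == "insertion"),
      n_del = sum(tab$indels$type == "deletion"),
      rq = if (is.null(q) || length(q) == 0) NA_real_ else rq_score(q),
      stringsAsFactors = FALSE)
  }
  structure(list(per_read = do.call(rbind, per),
                 substitutions = do.call(rbind, subs),
                 indels = do.call(rbind, inds),
                 alignments = alns),
            class = "error_analysis")
}

#' @export
print.error_analysis <- function(x, ...) {
  s <- summarize_errors(x)
  cat(sprintf("<error_analysis> %d read(s), overall error rate %.4g%%\n",
              nrow(x$per_read), 100 * s$error_rate))
  invisible(x)
}

#' Summarize a defined-community error analysis
#'
#' Computes per-reference read counts, error totals by type, the overall
#' per-base error rate (errors / aligned reference bases), the error-free
#' read fraction, the fraction of reads with indels, and per-rQ-bin
#' (floor of rQ) error rates. Subsetting options reproduce re-analyses
#' without recomputing alignments: drop listed read ids (e.g. vetted
#' chimeras/contaminants), restrict to reads with given reverse-primer
#' difference counts, or to reads at or above an rQ threshold.
#'
#' @param ea an `error_analysis`.
#' @param exclude_ids read ids to drop.
#' @param rev_diffs optional named integer vector (read id ->
#'   reverse-primer differences, from a [process_run()] audit) enabling
#'   `rev_diff` filtering.
#' @param rev_diff keep only reads with these difference counts.
#' @param min_rq keep only reads with rQ >= this value.
#' @return an `error_summary` list.
#' @export
summarize_errors <- function(ea, exclude_ids = NULL, rev_diffs = NULL,
                             rev_diff = NULL, min_rq = NULL) {
  per <- ea$per_read
  if (!is.null(exclude_ids)) per <- per[!(per$id %in% exclude_ids), ]
  if (!is.null(rev_diff)) {
    if (is.null(rev_diffs)) {
      stop("rev_diff filtering needs the rev_diffs id->count vector",
           call. = FALSE)
    }
    per <- per[per$id %in% names(rev_diffs)[rev_diffs %in% rev_diff], ]
  }
  if (!is.null(min_rq)) per <- per[!is.na(per$rq) & per$rq >= min_rq, ]
  nerr <- per$n_sub + per$n_ins + per$n_del
  bins <- if (all(is.na(per$rq))) NULL else {
    bin <- floor(per$rq)
    ok <- !is.na(bin)
    agg <- stats::aggregate(
      cbind(errors = nerr[ok], bases = per$ref_bases[ok], reads = 1L),
      by = list(rq_bin = bin[ok]), FUN = sum)
    agg$rate <- agg$errors / agg$bases
    agg
  }
  structure(list(
    n_reads = nrow(per),
    reads_per_reference = table(factor(per$ref_id)),
    total_substitutions = sum(per$n_sub),
    total_insertions = sum(per$n_ins),
    total_deletions = sum(per$n_del),
    aligned_ref_bases = sum(per$ref_bases),
    error_rate = if (nrow(per) == 0) NA_real_ else
      sum(nerr) / sum(per$ref_bases),
    error_free_reads = sum(nerr == 0),
    error_free_fraction = if (nrow(per) == 0) NA_real_ else
      mean(nerr == 0),
    indel_read_fraction = if (nrow(per) == 0) NA_real_ else
      mean(per$n_ins + per$n_del > 0),
    rq_bins = bins), class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat("<error_summary>\n")
  cat(sprintf("  reads: %d (error-free %.1f%%, with indels %.1f%%)\n",
              x$n_reads, 100 * x$error_free_fraction,
              100 * x$indel_read_fraction))
  cat(sprintf("  errors: %d sub, %d ins, %d del over %d reference bases\n",
              x$total_substitutions, x$total_insertions, x$total_deletions,
              x$aligned_ref_bases))
  cat(sprintf("  overall error rate per base: %.4g%%\n", 100 * x$error_rate))
  invisible(x)
}

#' Flag reads far from every community reference
#'
#' Reads whose per-base difference to their best reference
#' ((substitutions + insertions + deletions) / aligned reference length)
#' is at least `threshold` are candidates for external chimera or
#' contaminant vetting. Error-free reads are never flagged.
#'
#' @param ea an `error_analysis`.
#' @param threshold per-base difference threshold (default 0.10).
#' @return character vector of flagged read ids.
#' @export
flag_outliers <- function(ea, threshold = 0.10) {
  per <- ea$per_read
  nerr <- per$n_sub + per$n_ins + per$n_del
  rate <- nerr / per$ref_bases
  per$id[nerr >= 1L & rate >= threshold]
}

#' Write the five error-analysis output files
#'
#' `alignments.txt` (pairwise alignments), `substitutions.tsv`,
#' `indels.tsv`, `rq.tsv` (when quality was available) and `summary.txt`.
#'
#' @param ea an `error_analysis`.
#' @param out_dir output directory (created).
#' @return invisibly `out_dir`.
#' @export
write_error_analysis <- function(ea, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(out_dir, "alignments.txt"), "w")
  for (id in names(ea$alignments)) {
    al <- ea$alignments[[id]]
    writeLines(c(sprintf(">%s vs %s score %d", id, al$ref_id, al$score),
                 paste0("read ", al$read_aln),
                 paste0("ref  ", al$ref_aln), ""), con)
  }
  close(con)
  utils::write.table(ea$substitutions, file.path(out_dir, "substitutions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ea$indels, file.path(out_dir, "indels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!all(is.na(ea$per_read$rq))) {
    utils::write.table(ea$per_read[, c("id", "rq")],
                       file.path(out_dir, "rq.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  s <- summarize_errors(ea)
  con <- file(file.path(out_dir, "summary.txt"), "w")
  writeLines(c(
    sprintf("reads\t%d", s$n_reads),
    sprintf("substitutions\t%d", s$total_substitutions),
    sprintf("insertions\t%d", s$total_insertions),
    sprintf("deletions\t%d", s$total_deletions),
    sprintf("aligned_reference_bases\t%d", s$aligned_ref_bases),
    sprintf("error_rate_per_base\t%.6g", s$error_rate),
    sprintf("error_free_fraction\t%.6g", s$error_free_fraction),
    sprintf("indel_read_fraction\t%.6g", s$indel_read_fraction),
    "", "reads_per_reference:"), con)
  for (r in names(s$reads_per_reference)) {
    writeLines(sprintf("%s\t%d", r, s$reads_per_reference[[r]]), con)
  }
  if (!is.null(s$rq_bins)) {
    writeLines(c("", "rq_bin\treads\terrors\tbases\trate"), con)
    b <- s$rq_bins
    writeLines(sprintf("%d\t%d\t%d\t%d\t%.6g", b$rq_bin, b$reads,
                       b$errors, b$bases, b$rate), con)
  }
  close(con)
  invisible(out_dir)
}
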