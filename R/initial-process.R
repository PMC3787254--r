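#' Quality-filter configuration
#'
#' The five ordered read filters applied after demultiplexing:
#' forward primer, reverse primer, ambiguous bases (N), length, and read
#' quality (rQ). Defaults follow common practice for 454-style functional
#' gene amplicons.
#'
#' @param max_fwd_diff maximum differences (substitutions + indels) to the
#'   best forward primer (default 2).
#' @param max_rev_diff maximum differences to the reverse primer (default 1).
#' @param max_n maximum number of uncalled bases in the trimmed read
#'   (default 0).
#' @param min_length minimum trimmed read length in bases (default 150);
#'   the primer portion is not counted unless `keep_primer`.
#' @param min_rq minimum rQ score (default 20); skipped when the input has
#'   no quality scores.
#' @param keep_primer keep the matched primer regions on the trimmed read.
#' @return a `filter_config` list.
#' @export
filter_config <- function(max_fwd_diff = 2L, max_rev_diff = 1L, max_n = 0L,
                          min_length = 150L, min_rq = 20, keep_primer = FALSE) {
  stopifnot(max_fwd_diff >= 0, max_rev_diff >= 0, max_n >= 0,
            min_length >= 0, min_rq >= 0)
  structure(list(max_fwd_diff = as.integer(max_fwd_diff),
                 max_rev_diff = as.integer(max_rev_diff),
                 max_n = as.integer(max_n),
                 min_length = as.integer(min_length),
                 min_rq = as.numeric(min_rq),
                 keep_primer = isTRUE(keep_primer)),
            class = "filter_config")
}

#' Primer set
#'
#' @param forward one or more forward primers (IUPAC ambiguity codes
#'   allowed); at least one is required.
#' @param reverse optional reverse primers (given 5'->3' on the opposite
#'   strand, as ordered from the synthesis house); may be empty, in which
#'   case the reverse primer filter is not applied.
#' @return a `primer_set` list with normalized primers.
#' @export
primer_set <- function(forward, reverse = character(0)) {
  forward <- normalize_bases(forward)
  reverse <- normalize_bases(reverse)
  if (length(forward) < 1) stop("at least one forward primer is required",
                                call. = FALSE)
  check_iupac(forward)
  if (length(reverse) > 0) check_iupac(reverse)
  structure(list(forward = forward, reverse = reverse), class = "primer_set")
}

#' Read quality (rQ) score
#'
#' Summarizes per-base Phred scores as `rQ = -10 * log10(E)` where `E` is
#' the mean of the per-base error probabilities `10^(-Q_i/10)`. A read
#' whose bases all have Q = q has rQ = q exactly; a single low-quality
#' base pulls rQ down much harder than the arithmetic mean of Q would.
#'
#' @param quals integer vector of Phred Q scores (nonempty).
#' @return the rQ score.
#' @export
rq_score <- function(quals) {
  if (length(quals) == 0) stop("rQ is undefined for an empty quality vector",
                               call. = FALSE)
  -10 * log10(mean(10^(-as.numeric(quals) / 10)))
}

#' Find the best forward-primer match near the 5' end of a read
#'
#' Differences are unit-cost edit distance; a primer IUPAC ambiguity code
#' matches any base it encodes at zero cost, while an N in the read
#' matches nothing. The primer must begin within the first
#' `primer length + max_diff` bases of the (tag-stripped) read. The best
#' match is the lowest-difference, then leftmost, then first-listed
#' primer.
#'
#' @param bases read sequence (normalized, tag already removed).
#' @param primers character vector of forward primers.
#' @param max_diff maximum allowed differences.
#' @return list with `found`, and when found `start`, `end` (1-based,
#'   inclusive), `diff`, `primer` (index into `primers`).
#' @export
match_forward_primer <- function(bases, primers, max_diff) {
  best <- NULL
  for (k in seq_along(primers)) {
    p <- primers[k]
    win <- substr(bases, 1L, 2L * (nchar(p) + max_diff))
    if (!nzchar(win)) next
    hit <- cpp_semiglobal(p, win, 1L)
    if (hit$dist > max_diff) next
    if (is.null(best) || hit$dist < best$diff ||
        (hit$dist == best$diff && hit$end < best$end)) {
      best <- list(found = TRUE, start = hit$start, end = hit$end,
                   diff = hit$dist, primer = k)
    }
  }
  if (is.null(best)) list(found = FALSE) else best
}

#' Find the reverse-primer match at the 3' end of a read
#'
#' The supplied reverse primers are reverse-complemented and searched in
#' the forward-trimmed read. A full-primer best match with at most
#' `max_diff` differences wins; failing that, a relaxed heuristic looks
#' for a primer prefix terminating at the final base of the read, scored
#' +1 per matching base and -6 per difference (substitutions only), and
#' accepts the match iff the total weight is at least 6. No differences
#' are allowed in the heuristic if `max_diff` is 0.
#'
#' @param bases forward-trimmed read sequence.
#' @param primers reverse primers as supplied (not complemented).
#' @param max_diff maximum allowed differences.
#' @return list with `found`, and when found `start`, `end`, `diff`,
#'   `primer`, `partial` (TRUE when the relaxed prefix heuristic fired).
#' @export
match_reverse_primer <- function(bases, primers, max_diff) {
  rc <- revcomp(primers)
  n <- nchar(bases)
  best <- NULL
  for (k in seq_along(rc)) {
    hit <- cpp_semiglobal(rc[k], bases, 1L)
    if (hit$dist > max_diff) next
    if (is.null(best) || hit$dist < best$diff ||
        (hit$dist == best$diff && hit$end < best$end)) {
      best <- list(found = TRUE, start = hit$start, end = hit$end,
                   diff = hit$dist, primer = k, partial = FALSE)
    }
  }
  if (!is.null(best)) return(best)
  # relaxed prefix heuristic: primer prefix flush with the read's 3' end
  for (k in seq_along(rc)) {
    pch <- strsplit(rc[k], "", fixed = TRUE)[[1]]
    pbits <- iupac_bits_of(rc[k])
    for (L in seq_len(min(length(pch), n))) {
      tail_s <- substr(bases, n - L + 1L, n)
      tch <- strsplit(tail_s, "", fixed = TRUE)[[1]]
      tbits <- iupac_bits_of(tail_s)
      concrete <- tbits %in% c(1L, 2L, 4L, 8L)
      m <- sum(concrete & bitwAnd(pbits[seq_len(L)], tbits) > 0L)
      d <- L - m
      w <- m - 6L * d
      if (w >= 6L && d <= max_diff) {
        cand <- list(found = TRUE, start = n - L + 1L, end = n,
                     diff = d, primer = k, partial = TRUE, weight = w)
        if (is.null(best) || cand$diff < best$diff ||
            (cand$diff == best$diff && cand$weight > best$weight)) {
          best <- cand
        }
      }
    }
  }
  if (is.null(best)) list(found = FALSE) else best
}

match_tag <- function(bases, tags) {
  for (i in seq_along(tags$tag)) {
    if (startsWith(bases, tags$tag[i])) return(i)
  }
  NA_integer_
}

FILTER_ORDER <- c("forward_primer", "reverse_primer", "n", "length", "rq")

#' Demultiplex and filter a single read
#'
#' Applies tag identification and the five filters strictly in order
#' (forward primer, reverse primer, N, length, rQ); a failing read names
#' exactly one filter -- the first it failed. The rQ filter is skipped
#' when the read carries no quality scores.
#'
#' @param id read id.
#' @param bases read sequence (normalized).
#' @param quals integer quality vector or `NULL`.
#' @param tags a `tag_table` or `NULL` (single-sample run).
#' @param primers a [primer_set()].
#' @param config a [filter_config()].
#' @return list: `sample` (or `"NoTag"`), `passed`, `failed_filter`,
#'   trimmed `bases`/`quals` when passed, primer-match details, `length`,
#'   `rq`.
#' @export
process_read <- function(id, bases, quals = NULL, tags = NULL, primers,
                         config = filter_config()) {
  res <- list(id = id, sample = NA_character_, passed = FALSE,
              failed_filter = NA_character_, fwd_primer = NA_integer_,
              fwd_diff = NA_integer_, rev_primer = NA_integer_,
              rev_diff = NA_integer_, length = NA_integer_, rq = NA_real_)
  if (!is.null(tags)) {
    ti <- match_tag(bases, tags)
    if (is.na(ti)) {
      res$sample <- "NoTag"
      return(res)
    }
    res$sample <- tags$sample[ti]
    tl <- nchar(tags$tag[ti])
    bases <- substr(bases, tl + 1L, nchar(bases))
    if (!is.null(quals)) quals <- quals[-seq_len(tl)]
  } else {
    res$sample <- ""
  }
  fwd <- match_forward_primer(bases, primers$forward, config$max_fwd_diff)
  if (!fwd$found) {
    res$failed_filter <- "forward_primer"
    return(res)
  }
  res$fwd_primer <- fwd$primer
  res$fwd_diff <- fwd$diff
  keep5 <- if (config$keep_primer) fwd$start else fwd$end + 1L
  bases <- substr(bases, keep5, nchar(bases))
  if (!is.null(quals)) {
    quals <- if (keep5 <= length(quals)) {
      quals[seq.int(keep5, length(quals))]
    } else integer(0)
  }
  if (length(primers$reverse) > 0) {
    rev <- match_reverse_primer(bases, primers$reverse, config$max_rev_diff)
    if (!rev$found) {
      res$failed_filter <- "reverse_primer"
      return(res)
    }
    res$rev_primer <- rev$primer
    res$rev_diff <- rev$diff
    keep3 <- if (config$keep_primer) rev$end else rev$start - 1L
    bases <- substr(bases, 1L, keep3)
    if (!is.null(quals)) quals <- quals[seq_len(keep3)]
  }
  if (lengths(regmatches(bases, gregexpr("N", bases, fixed = TRUE))) >
      config$max_n) {
    res$failed_filter <- "n"
    return(res)
  }
  res$length <- nchar(bases)
  if (nchar(bases) < config$min_length) {
    res$failed_filter <- "length"
    return(res)
  }
  if (!is.null(quals) && length(quals) > 0) {
    res$rq <- rq_score(quals)
    if (res$rq < config$min_rq) {
      res$failed_filter <- "rq"
      return(res)
    }
  }
  res$passed <- TRUE
  res$bases <- bases
  res$quals <- quals
  res
}

#' Demultiplex and filter a sequencing run
#'
#' Runs [process_read()] over one or more read files and writes, per
#' sample (plus `NoTag`), trimmed FASTA (and QUAL when the input carried
#' quality), a failed-read listing naming the failing filter, a
#' best-primer/difference listing, length and quality statistics, and a
#' run summary with per-filter counts in filter order.
#'
#' @param read_files input FASTA/FASTQ files, or an [amp_reads] object.
#' @param tags optional `tag_table` (from [parse_tag_table()]).
#' @param primers a [primer_set()].
#' @param config a [filter_config()].
#' @param out_dir output directory (created); `NULL` for no file output.
#' @param qual_files optional QUAL files parallel to FASTA `read_files`.
#' @return a `filter_report`: list with `reads` (per-read audit
#'   data.frame), `summary` (per-sample per-filter counts), and `passed`
#'   (an [amp_reads] of trimmed passing reads).
#' @export
process_run <- function(read_files, tags = NULL, primers,
                        config = filter_config(), out_dir = NULL,
                        qual_files = NULL) {
  reads <- if (inherits(read_files, "amp_reads")) {
    read_files
  } else {
    parts <- lapply(seq_along(read_files), function(i) {
      load_reads(read_files[i],
                 qual_path = if (!is.null(qual_files)) qual_files[i])
    })
    do.call(c, parts)
  }
  rows <- vector("list", length(reads))
  passed_idx <- integer(0)
  out_bases <- character(0)
  out_quals <- list()
  out_samples <- character(0)
  out_ids <- character(0)
  for (i in seq_len(length(reads))) {
    q <- if (has_quals(reads)) reads$quals[[i]] else NULL
    r <- process_read(reads$id[i], reads$bases[i], q, tags, primers, config)
    rows[[i]] <- data.frame(
      id = r$id, sample = r$sample, passed = r$passed,
      failed_filter = r$failed_filter, fwd_primer = r$fwd_primer,
      fwd_diff = r$fwd_diff, rev_primer = r$rev_primer,
      rev_diff = r$rev_diff, length = r$length, rq = r$rq,
      stringsAsFactors = FALSE)
    if (r$passed) {
      out_ids <- c(out_ids, r$id)
      out_bases <- c(out_bases, r$bases)
      out_quals[[length(out_quals) + 1L]] <- r$quals
      out_samples <- c(out_samples, r$sample)
    }
  }
  audit <- do.call(rbind, rows)
  passed <- amp_reads(out_ids, out_bases,
                      if (has_quals(reads)) out_quals else NULL,
                      out_samples)
  # per-sample summary in fixed filter order
  samples <- sort(unique(audit$sample))
  summ <- do.call(rbind, lapply(samples, function(s) {
    sub <- audit[audit$sample == s, , drop = FALSE]
    cnt <- vapply(FILTER_ORDER, function(f) {
      sum(!is.na(sub$failed_filter) & sub$failed_filter == f)
    }, integer(1))
    data.frame(sample = s, matched_tag = nrow(sub),
               passed = sum(sub$passed), t(cnt),
               stringsAsFactors = FALSE, check.names = FALSE)
  }))
  report <- structure(list(reads = audit, summary = summ, passed = passed,
                           rq_available = has_quals(reads)),
                      class = "filter_report")
  if (!is.null(out_dir)) write_filter_report(report, out_dir)
  report
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  print(x$summary, row.names = FALSE)
  if (!x$rq_available) cat("  note: no quality scores; rq filter skipped\n")
  invisible(x)
}

write_filter_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (s in unique(report$reads$sample)) {
    sdir <- file.path(out_dir, if (nzchar(s)) s else "default")
    dir.create(sdir, showWarnings = FALSE)
    sub <- report$reads[report$reads$sample == s, , drop = FALSE]
    keep <- report$passed$sample == s
    if (any(keep)) {
      pr <- report$passed[keep]
      write_reads(pr, file.path(sdir, "trimmed.fasta"),
                  qual_path = if (report$rq_available)
                    file.path(sdir, "trimmed.qual"))
    }
    failed <- sub[!sub$passed & !is.na(sub$failed_filter), c("id", "failed_filter")]
    utils::write.table(failed, file.path(sdir, "failed.txt"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(sub[, c("id", "fwd_primer", "fwd_diff",
                               "rev_primer", "rev_diff")],
                       file.path(sdir, "primers.txt"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    stats <- c(
      sprintf("reads\t%d", nrow(sub)),
      sprintf("passed\t%d", sum(sub$passed)),
      sprintf("mean_length\t%.2f", mean(sub$length, na.rm = TRUE)),
      sprintf("median_length\t%s",
              format(stats::median(sub$length, na.rm = TRUE))),
      sprintf("mean_rq\t%.2f", mean(sub$rq, na.rm = TRUE)))
    writeLines(stats, file.path(sdir, "stats.txt"))
  }
  con <- file(file.path(out_dir, "summary.txt"), "w")
  on.exit(close(con))
  writeLines(paste(colnames(report$summary), collapse = "\t"), con)
  utils::write.table(report$summary, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!report$rq_available) {
    writeLines("# no quality scores supplied; rq filter skipped", con)
  }
  invisible(out_dir)
}
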