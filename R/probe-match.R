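#' Search an oligonucleotide probe/primer against target sequences
#'
#' Finds, for each target, the best occurrence of the query under a
#' semiglobal alignment: the query must be consumed in full, the target
#' ends are free, and substitutions and indels each cost 1. With
#' `allow_ambiguity`, a position matches whenever the IUPAC sets of the
#' two characters intersect; otherwise characters must be identical. For
#' a reverse primer (`reverse = TRUE`) the reverse complement of the
#' query is searched, so hits land on the plus strand of the target.
#' Only the best hit per target (lowest distance, then leftmost) is
#' reported, and only when its distance is at most `max_distance`.
#'
#' @param query oligo sequence (IUPAC ambiguity codes allowed).
#' @param targets named character vector of target sequences, or an
#'   [amp_reads] object.
#' @param max_distance maximum allowed differences (default 2).
#' @param allow_ambiguity match by IUPAC set intersection (default TRUE).
#' @param reverse search the reverse complement of the query.
#' @return data.frame with one row per hit: `target`, `distance`,
#'   `start`, `end` (1-based target positions), `query_aln`,
#'   `target_aln`, and `marks` (`|` match, `.` difference).
#' @export
probe_search <- function(query, targets, max_distance = 2L,
                         allow_ambiguity = TRUE, reverse = FALSE) {
  if (!nzchar(query)) stop("empty query", call. = FALSE)
  query <- normalize_bases(query)
  check_iupac(query)
  if (inherits(targets, "amp_reads")) {
    targets <- stats::setNames(targets$bases, targets$id)
  }
  if (length(targets) == 0) stop("empty target set", call. = FALSE)
  if (is.null(names(targets))) {
    names(targets) <- paste0("target", seq_along(targets))
  }
  targets <- normalize_bases(targets)
  q <- if (reverse) revcomp(query) else query
  mode <- if (allow_ambiguity) 2L else 0L
  rows <- lapply(names(targets), function(nm) {
    hit <- cpp_semiglobal(q, targets[[nm]], mode)
    if (hit$dist > max_distance) return(NULL)
    qa <- strsplit(hit$aligned_query, "", fixed = TRUE)[[1]]
    ta <- strsplit(hit$aligned_target, "", fixed = TRUE)[[1]]
    ok <- qa != "-" & ta != "-" &
      if (allow_ambiguity) {
        bq <- .iupac_bits[qa]; bt <- .iupac_bits[ta]
        !is.na(bq) & !is.na(bt) & bitwAnd(ifelse(is.na(bq), 0L, bq),
                                          ifelse(is.na(bt), 0L, bt)) > 0L
      } else {
        qa == ta
      }
    data.frame(target = nm, distance = hit$dist, start = hit$start,
               end = hit$end, query_aln = hit$aligned_query,
               target_aln = hit$aligned_target,
               marks = paste(ifelse(ok, "|", "."), collapse = ""),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(data.frame(target = character(0), distance = integer(0),
                      start = integer(0), end = integer(0),
                      query_aln = character(0), target_aln = character(0),
                      marks = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
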