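#' Collapse exact duplicate sequences
#'
#' Identical sequence strings (after normalization: uppercase, U to T) are
#' collapsed to one representative record -- the first seen -- so that
#' expensive downstream analyses run once per distinct string. The id
#' mapping records, one line per unique sequence in order of first
#' occurrence, the ids of all reads sharing that string; the sample
#' mapping records the sample (input file) of every input read.
#'
#' @param reads an [amp_reads] object (its `sample` field supplies the
#'   sample mapping), or a character vector of file paths to load.
#' @return list with `unique` ([amp_reads] of representatives, keeping the
#'   representative's own qualities), `id_map` (list of character vectors,
#'   first element the representative), and `sample_map` (data.frame
#'   `id`, `sample`).
#' @export
dereplicate <- function(reads) {
  if (is.character(reads)) {
    reads <- do.call(c, lapply(reads, load_reads))
  }
  if (length(reads) == 0) {
    return(list(unique = reads, id_map = list(),
                sample_map = data.frame(id = character(0),
                                        sample = character(0))))
  }
  first <- !duplicated(reads$bases)
  key <- match(reads$bases, reads$bases[first])
  id_map <- unname(split(reads$id, key))
  # split() orders by key value, which is already first-occurrence order
  list(unique = reads[first],
       id_map = id_map,
       sample_map = data.frame(id = reads$id, sample = reads$sample,
                               stringsAsFactors = FALSE))
}

#' Re-inflate dereplicated results ("explode")
#'
#' Given per-representative results and the mappings from
#' [dereplicate()], every original read id receives its representative's
#' record, partitioned by sample.
#'
#' @param results a named list/vector keyed by representative id (any
#'   per-sequence result: sequences, assignments, ...).
#' @param id_map id mapping from [dereplicate()].
#' @param sample_map sample mapping from [dereplicate()].
#' @return data.frame with columns `id`, `sample`, and a `result` list
#'   column (or plain column when results are scalar).
#' @export
explode <- function(results, id_map, sample_map) {
  reps <- vapply(id_map, `[`, character(1), 1L)
  missing <- setdiff(reps, names(results))
  if (length(missing) > 0) {
    stop("no result for representative '", missing[1], "'", call. = FALSE)
  }
  all_ids <- unlist(id_map, use.names = FALSE)
  bad <- setdiff(all_ids, sample_map$id)
  if (length(bad) > 0) {
    stop("id '", bad[1], "' missing from the sample mapping", call. = FALSE)
  }
  rep_of <- rep(reps, lengths(id_map))
  out <- data.frame(id = all_ids,
                    sample = sample_map$sample[match(all_ids, sample_map$id)],
                    stringsAsFactors = FALSE)
  res <- results[rep_of]
  if (is.list(res) && all(lengths(res) == 1L) &&
      all(vapply(res, is.atomic, logical(1)))) {
    res <- unlist(res, use.names = FALSE)
  }
  out$result <- res
  out[order(out$sample, match(out$id, all_ids)), , drop = FALSE]
}

#' Write / read dereplication mappings
#'
#' The id mapping file holds one whitespace-separated id list per line
#' (representative first); the sample mapping one `id sample` pair per
#' line.
#'
#' @param id_map,sample_map mappings from [dereplicate()].
#' @param ids_path,samples_path file paths.
#' @return invisibly the path written; readers return the mapping.
#' @export
write_id_map <- function(id_map, ids_path) {
  writeLines(vapply(id_map, paste, character(1), collapse = " "), ids_path)
  invisible(ids_path)
}

#' @rdname write_id_map
#' @export
read_id_map <- function(ids_path) {
  lines <- sub("\r$", "", readLines(ids_path, warn = FALSE))
  strsplit(lines[nzchar(lines)], "\\s+")
}

#' @rdname write_id_map
#' @export
write_sample_map <- function(sample_map, samples_path) {
  writeLines(paste(sample_map$id, sample_map$sample), samples_path)
  invisible(samples_path)
}

#' @rdname write_id_map
#' @export
read_sample_map <- function(samples_path) {
  lines <- sub("\r$", "", readLines(samples_path, warn = FALSE))
  parts <- strsplit(lines[nzchar(lines)], "\\s+")
  data.frame(id = vapply(parts, `[`, character(1), 1L),
             sample = vapply(parts, `[`, character(1), 2L),
             stringsAsFactors = FALSE)
}
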