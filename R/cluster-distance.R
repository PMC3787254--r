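#' Pairwise uncorrected distance over comparable columns
#'
#' The fraction of mismatching positions among comparable (non-insert)
#' alignment columns at which both records carry a residue; columns where
#' either record has a gap are excluded from numerator and denominator
#' (pairwise deletion). Comparison is case-insensitive; two characters
#' match when equal or when both are IUPAC codes whose base sets
#' intersect. Pairs sharing fewer than `min_overlap` compared positions
#' have no defined distance and raise an error naming the pair.
#'
#' @param maln a `masked_aln`.
#' @param a,b record ids or indices.
#' @param min_overlap minimum compared positions (default 25).
#' @return distance in `[0, 1]`.
#' @export
pairwise_distance <- function(maln, a, b, min_overlap = 25L) {
  m <- aln_char_matrix(maln)
  ia <- if (is.character(a)) match(a, maln$ids) else a
  ib <- if (is.character(b)) match(b, maln$ids) else b
  if (is.na(ia) || is.na(ib)) stop("record not found in alignment",
                                   call. = FALSE)
  pair_dist(m[ia, ], m[ib, ], maln$ids[ia], maln$ids[ib], min_overlap)
}

aln_char_matrix <- function(maln) {
  cols <- comparable_columns(maln)
  ch <- strsplit(maln$seqs, "", fixed = TRUE)
  t(vapply(ch, function(x) x[cols], character(length(cols))))
}

pair_dist <- function(ra, rb, ida, idb, min_overlap) {
  ok <- !(ra %in% c("-", ".")) & !(rb %in% c("-", "."))
  n <- sum(ok)
  if (n < max(1L, min_overlap)) {
    stop("distance undefined for pair ", ida, " / ", idb, ": only ", n,
         " compared position(s), fewer than the minimum overlap of ",
         min_overlap, call. = FALSE)
  }
  x <- ra[ok]
  y <- rb[ok]
  eq <- x == y
  if (!all(eq)) {
    bx <- .iupac_bits[x[!eq]]
    by <- .iupac_bits[y[!eq]]
    amb <- !is.na(bx) & !is.na(by) & bitwAnd(bx, by) > 0L
    eq[!eq] <- amb
  }
  sum(!eq) / n
}

#' Full pairwise distance matrix of a masked alignment
#'
#' Convenience for desk-scale inputs and for oracle comparisons; the
#' streaming path ([edge_stream()]) does not require the full matrix in
#' memory conceptually, though this implementation materializes it before
#' the disk sort.
#'
#' @param maln a `masked_aln`.
#' @param min_overlap minimum compared positions per pair.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(maln, min_overlap = 25L) {
  m <- aln_char_matrix(maln)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(maln$ids, maln$ids))
  if (n < 2) return(d)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d[i, j] <- d[j, i] <- pair_dist(m[i, ], m[j, ], maln$ids[i],
                                      maln$ids[j], min_overlap)
    }
  }
  d
}

#' Sorted thin-edge stream
#'
#' Computes all n(n-1)/2 pairwise distances (thin edges) and sorts them
#' in non-decreasing weight order, spilling sorted chunks to disk and
#' k-way merging them when more than `budget_edges` edges would be held
#' in memory at once. Ties are broken by (smaller index, larger index) so
#' the stream -- and hence every downstream merge -- is deterministic.
#'
#' @param maln a `masked_aln` (>= 2 records), or a precomputed symmetric
#'   distance matrix with dimnames.
#' @param min_overlap minimum compared positions per pair.
#' @param budget_edges maximum edges held in memory while sorting.
#' @param tmpdir scratch directory for sort chunks.
#' @return an `edge_stream`: list with `edges` (data.frame `i`, `j`, `w`
#'   sorted by weight), `ids`, `n`, and `gmax` (the largest pairwise
#'   distance, used for the average-linkage upper bound).
#' @export
edge_stream <- function(maln, min_overlap = 25L, budget_edges = Inf,
                        tmpdir = tempdir()) {
  d <- if (is.matrix(maln)) maln else distance_matrix(maln, min_overlap)
  ids <- rownames(d)
  n <- nrow(d)
  if (n < 2) stop("need at least two records to build an edge stream",
                  call. = FALSE)
  ut <- which(upper.tri(d), arr.ind = TRUE)
  edges <- data.frame(i = ut[, 1], j = ut[, 2], w = d[ut])
  if (is.finite(budget_edges) && nrow(edges) > budget_edges) {
    edges <- external_sort_edges(edges, budget_edges, tmpdir)
  } else {
    edges <- edges[order(edges$w, edges$i, edges$j), , drop = FALSE]
  }
  rownames(edges) <- NULL
  structure(list(edges = edges, ids = ids, n = n, gmax = max(edges$w)),
            class = "edge_stream")
}

# chunked external sort: sort blocks of <= budget edges, write each to a
# temporary file, then k-way merge reading one record per file at a time
external_sort_edges <- function(edges, budget, tmpdir) {
  # clamp the chunk count so the k-way merge never exhausts R's open
  # connection limit; the output stream is identical for every budget
  budget <- max(budget, ceiling(nrow(edges) / 64))
  nchunk <- ceiling(nrow(edges) / budget)
  files <- character(nchunk)
  for (k in seq_len(nchunk)) {
    rows <- seq.int((k - 1L) * budget + 1L, min(k * budget, nrow(edges)))
    blk <- edges[rows, , drop = FALSE]
    blk <- blk[order(blk$w, blk$i, blk$j), , drop = FALSE]
    files[k] <- tempfile("edges", tmpdir = tmpdir, fileext = ".tsv")
    utils::write.table(blk, files[k], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  on.exit(unlink(files))
  cons <- lapply(files, function(f) file(f, "r"))
  on.exit(lapply(cons, close), add = TRUE)
  heads <- lapply(cons, function(con) read_edge_line(con))
  out_i <- integer(nrow(edges)); out_j <- integer(nrow(edges))
  out_w <- numeric(nrow(edges))
  for (r in seq_len(nrow(edges))) {
    live <- which(!vapply(heads, is.null, logical(1)))
    hw <- vapply(heads[live], `[[`, numeric(1), "w")
    hi <- vapply(heads[live], `[[`, numeric(1), "i")
    hj <- vapply(heads[live], `[[`, numeric(1), "j")
    best <- live[order(hw, hi, hj)[1]]
    out_i[r] <- heads[[best]]$i
    out_j[r] <- heads[[best]]$j
    out_w[r] <- heads[[best]]$w
    heads[best] <- list(read_edge_line(cons[[best]]))
  }
  data.frame(i = out_i, j = out_j, w = out_w)
}

read_edge_line <- function(con) {
  ln <- readLines(con, n = 1L)
  if (length(ln) == 0) return(NULL)
  f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
  list(i = as.integer(f[1]), j = as.integer(f[2]), w = as.numeric(f[3]))
}
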