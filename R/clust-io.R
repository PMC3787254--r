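#' Multi-cutoff clustering result
#'
#' The in-memory model of an RDP-style `.clust` file: the sample roster,
#' per-sample sequence counts, and for every distance cutoff the cluster
#' membership, split per sample. Samples with no members in a cluster are
#' simply absent from that cluster's member list.
#'
#' @param samples ordered sample names.
#' @param sample_sizes integer count of sequences per sample.
#' @param levels list of levels; each a `list(cutoff =, clusters =)` where
#'   `clusters` is a list of `list(id = <int>, members = <named list of
#'   character id vectors, one per represented sample>)`.
#' @return an object of class `cluster_set`.
#' @export
cluster_set <- function(samples, sample_sizes, levels) {
  samples <- as.character(samples)
  sample_sizes <- as.integer(sample_sizes)
  if (length(samples) != length(sample_sizes)) {
    stop("samples/sample_sizes length mismatch", call. = FALSE)
  }
  for (lv in levels) {
    for (cl in lv$clusters) {
      extra <- setdiff(names(cl$members), samples)
      if (length(extra) > 0) {
        stop("cluster references unknown sample '", extra[1], "'",
             call. = FALSE)
      }
    }
  }
  structure(list(samples = samples, sample_sizes = sample_sizes,
                 levels = levels), class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cuts <- vapply(x$levels, `[[`, numeric(1), "cutoff")
  nclust <- vapply(x$levels, function(l) length(l$clusters), integer(1))
  cat(sprintf("<cluster_set> %d sample(s), %d sequence(s), %d level(s)\n",
              length(x$samples), sum(x$sample_sizes), length(x$levels)))
  cat(sprintf("  cutoffs %s ... %s; clusters %d ... %d\n",
              format(min(cuts)), format(max(cuts)),
              max(nclust), min(nclust)))
  invisible(x)
}

clust_cutoffs <- function(cs) vapply(cs$levels, `[[`, numeric(1), "cutoff")

clust_level <- function(cs, cutoff) {
  cuts <- clust_cutoffs(cs)
  i <- which(abs(cuts - cutoff) < 1e-9)
  if (length(i) != 1) {
    stop("cutoff ", format(cutoff), " not present; available: ",
         paste(format(cuts), collapse = " "), call. = FALSE)
  }
  cs$levels[[i]]
}

#' Write / read the RDP-style cluster file format
#'
#' Layout (tab-delimited where noted): line 1 the sample names, line 2 the
#' per-sample sequence counts; then for each cutoff a header line
#' `distance <cutoff> <n_clusters>` followed by one line per
#' (cluster, represented sample):
#' `<cluster_id>  <sample>  <n>  <id1 id2 ...>` with ids space-separated.
#' The format convention fixes the content but not the header token
#' layout; this writer fixes the layout above and the reader accepts it.
#'
#' @param cs a [cluster_set()].
#' @param path output (input) file.
#' @return `write_clust` returns `path` invisibly; `read_clust` a
#'   `cluster_set` such that `read_clust(write_clust(x)) == x`.
#' @export
write_clust <- function(cs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(cs$samples, collapse = "\t"), con)
  writeLines(paste(cs$sample_sizes, collapse = "\t"), con)
  for (lv in cs$levels) {
    writeLines(sprintf("distance %.10g %d", lv$cutoff, length(lv$clusters)),
               con)
    for (cl in lv$clusters) {
      for (s in names(cl$members)) {
        ids <- cl$members[[s]]
        if (length(ids) == 0) next  # empty sample lines are not emitted
        writeLines(paste(cl$id, s, length(ids),
                         paste(ids, collapse = " "), sep = "\t"), con)
      }
    }
  }
  invisible(path)
}

#' @rdname write_clust
#' @export
read_clust <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  if (length(lines) < 2) stop("truncated cluster file", call. = FALSE)
  samples <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  sizes <- suppressWarnings(
    as.integer(strsplit(lines[2], "\t", fixed = TRUE)[[1]]))
  if (anyNA(sizes)) stop("malformed sample size line (line 2)", call. = FALSE)
  levels <- list()
  i <- 3L
  while (i <= length(lines)) {
    if (!nzchar(lines[i])) { i <- i + 1L; next }
    hdr <- strsplit(lines[i], " ", fixed = TRUE)[[1]]
    if (length(hdr) != 3 || hdr[1] != "distance" ||
        is.na(suppressWarnings(as.numeric(hdr[2]))) ||
        is.na(suppressWarnings(as.integer(hdr[3])))) {
      stop("malformed level header at line ", i, ": '", lines[i], "'",
           call. = FALSE)
    }
    cutoff <- as.numeric(hdr[2])
    nclust <- as.integer(hdr[3])
    i <- i + 1L
    rows <- list()
    while (i <= length(lines) && nzchar(lines[i]) &&
           !startsWith(lines[i], "distance ")) {
      f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      if (length(f) != 4) {
        stop("malformed cluster line at line ", i, call. = FALSE)
      }
      rows[[length(rows) + 1L]] <- list(
        id = as.integer(f[1]), sample = f[2],
        ids = strsplit(f[4], " ", fixed = TRUE)[[1]])
      i <- i + 1L
    }
    cids <- unique(vapply(rows, `[[`, integer(1), "id"))
    clusters <- lapply(cids, function(cid) {
      sub <- rows[vapply(rows, function(r) r$id == cid, logical(1))]
      members <- lapply(sub, `[[`, "ids")
      names(members) <- vapply(sub, `[[`, character(1), "sample")
      list(id = cid, members = members)
    })
    if (length(clusters) != nclust) {
      stop("level at cutoff ", format(cutoff), " declares ", nclust,
           " clusters but lists ", length(clusters), call. = FALSE)
    }
    levels[[length(levels) + 1L]] <- list(cutoff = cutoff,
                                          clusters = clusters)
  }
  cluster_set(samples, sizes, levels)
}

#' Convert one clustering level to an OTU abundance matrix
#'
#' @param cs a [cluster_set()].
#' @param cutoff a distance cutoff present in `cs`.
#' @return integer matrix, one row per cluster (rownames = cluster ids),
#'   one column per sample; row sums are cluster sizes and column sums the
#'   per-sample sequence totals.
#' @export
clust_to_otu_matrix <- function(cs, cutoff) {
  lv <- clust_level(cs, cutoff)
  m <- matrix(0L, nrow = length(lv$clusters), ncol = length(cs$samples),
              dimnames = list(vapply(lv$clusters, `[[`, integer(1), "id"),
                              cs$samples))
  for (r in seq_along(lv$clusters)) {
    for (s in names(lv$clusters[[r]]$members)) {
      m[r, s] <- length(lv$clusters[[r]]$members[[s]])
    }
  }
  m
}

#' Write an OTU abundance matrix as TSV
#'
#' Header row of sample names, first column the cluster id.
#'
#' @param m matrix from [clust_to_otu_matrix()].
#' @param path output file.
#' @return invisibly `path`.
#' @export
write_otu_matrix <- function(m, path) {
  df <- data.frame(cluster = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
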