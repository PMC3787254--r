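# Independent oracles and fixture builders shared by the test files.
# Oracles deliberately avoid the package's own algorithms: exhaustive
# enumeration, base-R dynamic programming via utils::adist, stats::hclust,
# and closed-form arithmetic.

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# exhaustive global-alignment score: match +1, mismatch -1, gap -2;
# plain recursion over all alignments (strings must be short)
enum_nw_score <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- if (i == 0 && j == 0) {
      0
    } else {
      best <- -Inf
      if (i > 0 && j > 0) {
        s <- if (substr(a, i, i) == substr(b, j, j)) 1 else -1
        best <- max(best, rec(i - 1, j - 1) + s)
      }
      if (i > 0) best <- max(best, rec(i - 1, j) - 2)
      if (j > 0) best <- max(best, rec(i, j - 1) - 2)
      best
    }
    memo[[key]] <- v
    v
  }
  rec(nchar(a), nchar(b))
}

# brute-force semiglobal distance: the query against every substring of
# the target (plus the empty one), plain Levenshtein via utils::adist
brute_semiglobal_dist <- function(query, target) {
  n <- nchar(target)
  best <- nchar(query)  # empty occurrence: delete the whole query
  for (s in seq_len(n)) {
    for (e in seq.int(s, n)) {
      best <- min(best, utils::adist(query, substr(target, s, e)))
    }
  }
  best
}

# expand a short degenerate IUPAC oligo into all concrete realizations
iupac_expansions <- function(x) {
  sets <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
               Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
               K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
               D = c("A", "G", "T"), H = c("A", "C", "T"),
               V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  parts <- sets[strsplit(x, "", fixed = TRUE)[[1]]]
  apply(do.call(expand.grid, c(parts, stringsAsFactors = FALSE)), 1,
        paste, collapse = "")
}

# label each sequence with its cluster at a cutoff, for partition checks
partition_at <- function(cs, cutoff) {
  lv <- ampkit:::clust_level(cs, cutoff)
  out <- integer(0)
  for (cl in lv$clusters) {
    for (ids in cl$members) out[ids] <- cl$id
  }
  out
}

# TRUE when two labelings induce the same partition
same_partition <- function(x, y) {
  stopifnot(length(x) == length(y))
  tab <- table(x, y)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

random_distance_matrix <- function(n, lo = 0.01, hi = 0.99) {
  d <- matrix(0, n, n)
  # all-distinct off-diagonal values make agglomerative merges unambiguous
  d[upper.tri(d)] <- sample(seq(lo, hi, length.out = n * (n - 1) / 2))
  d <- d + t(d)
  rownames(d) <- colnames(d) <- sprintf("s%03d", seq_len(n))
  d
}

# naive agglomerative partition oracle via stats::hclust
hclust_partition <- function(d, method, cutoff) {
  hc <- stats::hclust(stats::as.dist(d), method = method)
  stats::cutree(hc, h = cutoff + 1e-9)
}

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# a small two-sample cluster_set used by several io tests
demo_cluster_set <- function() {
  cluster_set(
    samples = c("S1", "S2"), sample_sizes = c(3L, 2L),
    levels = list(
      list(cutoff = 0.0, clusters = list(
        list(id = 0L, members = list(S1 = c("a", "b"), S2 = "d")),
        list(id = 1L, members = list(S1 = "c")),
        list(id = 2L, members = list(S2 = "e")))),
      list(cutoff = 0.03, clusters = list(
        list(id = 0L, members = list(S1 = c("a", "b", "c"), S2 = "d")),
        list(id = 1L, members = list(S2 = "e"))))))
}
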