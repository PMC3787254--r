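toy_aln <- function(seqs, mask = NULL) {
  if (is.null(mask)) mask <- strrep("x", nchar(seqs[1]))
  masked_alignment(names(seqs), unname(seqs), mask)
}

test_that("pairwise uncorrected distance follows the column rules", {
  m <- toy_aln(c(a = "ACGT", b = "ACGA"))
  expect_equal(pairwise_distance(m, "a", "b", min_overlap = 1), 0.25)
  expect_equal(pairwise_distance(m, "a", "a", min_overlap = 1), 0)
  # a gap column is excluded from both numerator and denominator
  g <- toy_aln(c(a = "AC-T", b = "ACGT"))
  expect_equal(pairwise_distance(g, "a", "b", min_overlap = 1), 0)
  # insert columns (mask gaps) are never compared
  i <- toy_aln(c(a = "ACGTT", b = "ACCTT"), mask = "xx.xx")
  expect_equal(pairwise_distance(i, "a", "b", min_overlap = 1), 0)
  # intersecting IUPAC sets match; disjoint ones differ
  u <- toy_aln(c(a = "ARGT", b = "AAGT"))
  expect_equal(pairwise_distance(u, "a", "b", min_overlap = 1), 0)
  v <- toy_aln(c(a = "ARGT", b = "ACGT"))
  expect_equal(pairwise_distance(v, "a", "b", min_overlap = 1), 0.25)
  # no comparable overlap is a hard error naming the pair
  z <- toy_aln(c(a = "AC--", b = "--GT"))
  expect_error(pairwise_distance(z, "a", "b", min_overlap = 1), "a / b")
})

test_that("edge streams are the sorted distance multiset, any budget", {
  set.seed(101)
  n <- 50
  seqs <- character(n)
  base <- strsplit(random_seq(120), "")[[1]]
  for (i in seq_len(n)) {
    s <- base
    mut <- sample(120, sample(5:40, 1))
    s[mut] <- sample(c("A", "C", "G", "T"), length(mut), replace = TRUE)
    seqs[i] <- paste(s, collapse = "")
  }
  names(seqs) <- sprintf("r%02d", seq_len(n))
  maln <- toy_aln(seqs)
  es <- edge_stream(maln)
  d <- distance_matrix(maln)
  expect_equal(es$edges$w, sort(d[upper.tri(d)]))
  expect_false(is.unsorted(es$edges$w))
  expect_equal(es$gmax, max(d))
  # a 1-edge in-memory budget (fully external sort) gives the same stream
  es1 <- edge_stream(maln, budget_edges = 1)
  expect_equal(es1$edges, es$edges)
})

test_that("worked three-sequence examples merge at the textbook heights", {
  d <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d["A", "B"] <- d["B", "A"] <- 0.10
  d["A", "C"] <- d["C", "A"] <- 0.20
  d["B", "C"] <- d["C", "B"] <- 0.30
  es <- edge_stream(d)
  comp <- cluster_stream(es, "complete", max_cutoff = 0.4, step = 0.01)
  expect_equal(length(ampkit:::clust_level(comp, 0.09)$clusters), 3)
  expect_equal(length(ampkit:::clust_level(comp, 0.10)$clusters), 2)
  expect_equal(length(ampkit:::clust_level(comp, 0.29)$clusters), 2)
  expect_equal(length(ampkit:::clust_level(comp, 0.30)$clusters), 1)
  avg <- cluster_stream(es, "average", max_cutoff = 0.4, step = 0.01)
  expect_equal(length(ampkit:::clust_level(avg, 0.24)$clusters), 2)
  expect_equal(length(ampkit:::clust_level(avg, 0.25)$clusters), 1)
  sng <- cluster_stream(es, "single", max_cutoff = 0.4, step = 0.01)
  expect_equal(length(ampkit:::clust_level(sng, 0.20)$clusters), 1)
})

test_that("streaming clustering equals the naive agglomerative oracle", {
  set.seed(103)
  cutoffs <- seq(0, 1, by = 0.05)
  for (n in c(8, 20, 50)) {
    d <- random_distance_matrix(n)
    es <- edge_stream(d)
    for (meth in c("single", "complete", "average")) {
      cs <- cluster_stream(es, meth, max_cutoff = 1, step = 0.05)
      for (cut in cutoffs) {
        mine <- partition_at(cs, cut)[rownames(d)]
        want <- hclust_partition(d, meth, cut)
        expect_true(same_partition(mine, want),
                    info = sprintf("n=%d %s cut=%.2f", n, meth, cut))
      }
    }
  }
})

test_that("results are invariant to the thick-edge memory budget", {
  set.seed(107)
  d <- random_distance_matrix(16)
  es <- edge_stream(d)
  for (meth in c("complete", "average")) {
    full <- cluster_stream(es, meth, max_cutoff = 1, step = 0.05)
    tight <- cluster_stream(es, meth, max_cutoff = 1, step = 0.05,
                            budget = 3)
    multi <- cluster_stream(es, meth, max_cutoff = 1, step = 0.05,
                            budget = 3, scan = "multi")
    expect_identical(tight, full)
    expect_identical(multi, full)
  }
})

test_that("average-linkage bounds sandwich the exact thick-edge mean", {
  set.seed(109)
  d <- random_distance_matrix(12)
  es <- edge_stream(d)
  # assert_bounds() raises if lower > mean or upper < mean at any edge
  expect_no_error(cluster_stream(es, "average", max_cutoff = 1, step = 0.05,
                                 debug_bounds = TRUE, exact_dist = d))
})

test_that("partitions at larger cutoffs coarsen smaller ones", {
  set.seed(113)
  d <- random_distance_matrix(20)
  cs <- cluster_stream(edge_stream(d), "average", max_cutoff = 1,
                       step = 0.1)
  cuts <- seq(0, 1, by = 0.1)
  for (k in seq_along(cuts)[-1]) {
    fine <- partition_at(cs, cuts[k - 1])[rownames(d)]
    coarse <- partition_at(cs, cuts[k])[rownames(d)]
    # every fine cluster maps into exactly one coarse cluster
    expect_true(all(rowSums(table(fine, coarse) > 0) == 1))
  }
})

test_that("unsorted streams and degenerate inputs are handled", {
  d <- random_distance_matrix(5)
  es <- edge_stream(d)
  es$edges <- es$edges[rev(seq_len(nrow(es$edges))), ]
  expect_error(cluster_stream(es, "complete"), "unsorted")
  one <- toy_aln(c(only = strrep("ACGT", 10)))
  cs <- cluster_sequences(one, max_cutoff = 0.1, step = 0.05)
  expect_true(all(vapply(cs$levels, function(l) length(l$clusters),
                         integer(1)) == 1))
})

test_that("sample mapping splits cluster membership by sample", {
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d[upper.tri(d)] <- c(0.02, 0.3, 0.31, 0.32, 0.33, 0.04)
  d <- d + t(d)
  smap <- data.frame(id = letters[1:4],
                     sample = c("s1", "s1", "s2", "s2"))
  cs <- cluster_stream(edge_stream(d), "complete", max_cutoff = 0.1,
                       step = 0.05, sample_map = smap)
  expect_equal(cs$samples, c("s1", "s2"))
  expect_equal(cs$sample_sizes, c(2L, 2L))
  lv <- ampkit:::clust_level(cs, 0.05)
  expect_equal(length(lv$clusters), 2)
  expect_equal(sort(names(lv$clusters[[1]]$members)), "s1")
})

test_that("least-squares representatives minimize the squared distances", {
  seqs <- c(A = "AAAAAAAAAA", B = "AAAAAAAACC", C = "AAAACCCCCC")
  maln <- toy_aln(seqs)
  cs <- cluster_sequences(maln, "complete", max_cutoff = 0.8, step = 0.1,
                          min_overlap = 1)
  reps <- representative_sequences(cs, maln, 0.8, min_overlap = 1)
  # B has the smallest sum of squared distances (0.04 + 0.16 vs 0.04+0.36)
  expect_equal(reps$id, "B")
  # singleton clusters represent themselves
  reps0 <- representative_sequences(cs, maln, 0.0, min_overlap = 1)
  expect_equal(sort(reps0$id), c("A", "B", "C"))
  # ties break to the lexicographically smallest id
  tie <- toy_aln(c(b = "AAAA", a = "AAAA", c = "AAAA"))
  cst <- cluster_sequences(tie, "complete", max_cutoff = 0.1, step = 0.1,
                           min_overlap = 1)
  rept <- representative_sequences(cst, tie, 0.1, min_overlap = 1)
  expect_equal(rept$id, "a")
  # a member missing from the alignment is reported by name
  expect_error(representative_sequences(cst, toy_aln(c(a = "AAAA")), 0.1,
                                        min_overlap = 1), "'b'")
})
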