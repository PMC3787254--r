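test_that("rarefaction matches closed forms and Monte-Carlo resampling", {
  counts <- c(5, 5)
  rc <- rarefaction(counts)
  expect_equal(rc$richness[rc$k == 1], 1)
  expect_equal(rc$richness[rc$k == 10], 2)                 # full sample
  expect_equal(rc$richness[rc$k == 5], 2 * (1 - 1 / 252))  # closed form
  expect_error(rarefaction(c(0, 0)), "empty")
  # non-decreasing and bounded by observed richness
  set.seed(131)
  counts2 <- c(40, 20, 10, 5, 3, 1, 1)
  rc2 <- rarefaction(counts2)
  expect_true(all(diff(rc2$richness) >= -1e-12))
  expect_lte(max(rc2$richness), length(counts2))
  # Monte-Carlo oracle at k = N/4 and N/2
  N <- sum(counts2)
  pool <- rep(seq_along(counts2), counts2)
  for (k in c(N %/% 4, N %/% 2)) {
    draws <- replicate(4000, length(unique(sample(pool, k))))
    se <- stats::sd(draws) / sqrt(length(draws))
    expect_lt(abs(mean(draws) - rc2$richness[rc2$k == k]), 3 * se + 1e-9)
  }
})

test_that("Shannon index matches direct evaluation", {
  expect_equal(shannon(10), 0)
  expect_equal(shannon(rep(3, 4)), log(4))
  p <- c(1, 2, 3) / 6
  expect_equal(shannon(c(1, 2, 3)), -sum(p * log(p)))
  expect_equal(shannon(c(1, 2, 3)), 1.011404, tolerance = 1e-6)
  expect_equal(shannon(rep(2, 4), base = 2), 2)
  # invariant under OTU relabeling
  set.seed(137)
  v <- sample(1:20, 8)
  expect_equal(shannon(sample(v)), shannon(v))
})

test_that("Chao1 matches the formulas and dominates observed richness", {
  expect_equal(chao1(c(3, 4, 5)), 3)             # f1 = 0: no correction
  expect_equal(chao1(c(1, 1, 2, 5)), 4.5)        # 4 + 2*1/(2*(1+1))
  expect_equal(chao1(c(1, 1, 2, 5), bias_corrected = FALSE), 4 + 4 / 2)
  set.seed(139)
  for (i in 1:20) {
    v <- sample(1:5, sample(3:12, 1), replace = TRUE)
    expect_gte(chao1(v), sum(v > 0))
    expect_equal(chao1(sample(v)), chao1(v))
  }
})

test_that("Chao-corrected Jaccard/Sorensen match hand-evaluated cases", {
  x <- c(5, 3, 2, 2)
  y <- c(4, 2, 4, 0)
  # shared OTUs 1:3, all shared counts >= 2 in both: corrections vanish
  cs <- chao_shared_similarity(x, y)
  U <- 10 / 12
  V <- 1
  expect_equal(cs$U, U)
  expect_equal(cs$V, V)
  expect_equal(cs$jaccard, U * V / (U + V - U * V))
  expect_equal(cs$sorensen, 2 * U * V / (U + V))
  # identical samples: both indices 1
  id <- chao_shared_similarity(c(2, 3, 4), c(2, 3, 4))
  expect_equal(id$jaccard, 1)
  expect_equal(id$sorensen, 1)
  # disjoint samples: both 0
  expect_equal(chao_shared_similarity(c(2, 0), c(0, 3))$jaccard, 0)
  # correction kicks in when a shared OTU is a singleton in the other
  # sample; evaluate the printed formula directly as the oracle
  x2 <- c(6, 1, 3, 0)
  y2 <- c(1, 4, 2, 5)
  n <- sum(x2); m <- sum(y2)
  sh <- x2 > 0 & y2 > 0
  U2 <- sum(x2[sh]) / n + ((m - 1) / m) * (sum(sh & y2 == 1) /
        max(2 * sum(sh & y2 == 2), 2)) * sum(x2[sh & y2 == 1]) / n
  V2 <- sum(y2[sh]) / m + ((n - 1) / n) * (sum(sh & x2 == 1) /
        max(2 * sum(sh & x2 == 2), 2)) * sum(y2[sh & x2 == 1]) / m
  U2 <- min(U2, 1); V2 <- min(V2, 1)
  got <- chao_shared_similarity(x2, y2)
  expect_equal(got$jaccard, U2 * V2 / (U2 + V2 - U2 * V2))
  expect_equal(got$sorensen, 2 * U2 * V2 / (U2 + V2))
  expect_error(chao_shared_similarity(c(0, 0), c(1, 2)), "empty")
})

test_that("similarity indices stay in range with Sorensen >= Jaccard", {
  set.seed(149)
  for (i in 1:30) {
    x <- stats::rpois(12, 2)
    y <- stats::rpois(12, 2)
    if (sum(x) == 0 || sum(y) == 0) next
    cs <- chao_shared_similarity(x, y)
    expect_gte(cs$jaccard, 0); expect_lte(cs$jaccard, 1)
    expect_gte(cs$sorensen, 0); expect_lte(cs$sorensen, 1)
    expect_gte(cs$sorensen, cs$jaccard - 1e-12)
  }
})

test_that("UPGMA dendrograms use ultrametric half-distance heights", {
  sim <- matrix(c(1, 0.6, 0.6, 1), 2, 2,
                dimnames = list(c("A", "B"), c("A", "B")))
  tr <- upgma_dendrogram(sim)
  # two tips joined at height (1 - 0.6) / 2 = 0.2
  expect_equal(sort(tr$phylo$tip.label), c("A", "B"))
  expect_equal(unname(tr$phylo$edge.length), c(0.2, 0.2))
  # the clearly closest pair joins first
  sim3 <- matrix(c(1, 0.9, 0.2,
                   0.9, 1, 0.25,
                   0.2, 0.25, 1), 3, 3,
                 dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- upgma_dendrogram(sim3)
  phy <- tr3$phylo
  # A and B are siblings
  anc <- phy$edge[match(match(c("A", "B"), phy$tip.label), phy$edge[, 2]), 1]
  expect_equal(anc[1], anc[2])
  # naive UPGMA height oracle for the root: mean of (1-s) across the join
  root_h <- mean(c(1 - 0.2, 1 - 0.25)) / 2
  expect_equal(max(ape::node.depth.edgelength(phy)), root_h)
  # identical samples give a zero-height star
  simz <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  trz <- upgma_dendrogram(simz)
  expect_true(all(trz$phylo$edge.length == 0))
  expect_error(upgma_dendrogram(matrix(1, 1, 1)), "two or more")
})

test_that("alpha/beta tables flow from a cluster set end to end", {
  cs <- demo_cluster_set()
  ad <- alpha_diversity(cs)
  expect_equal(nrow(ad), 4)  # 2 cutoffs x 2 samples
  otu <- clust_to_otu_matrix(cs, 0.03)
  sims <- beta_similarity(otu)
  expect_equal(diag(sims$jaccard), c(S1 = 1, S2 = 1))
  out <- tempfile()
  write_diversity(cs, c(0.03), out)
  expect_true(file.exists(file.path(out, "alpha_diversity.tsv")))
  expect_true(file.exists(file.path(out, "jaccard_0.03.tsv")))
  expect_true(file.exists(file.path(out, "upgma_jaccard_0.03.nwk")))
  nw <- readLines(file.path(out, "upgma_jaccard_0.03.nwk"))
  expect_match(nw, "^\\(.*\\);$")
})
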