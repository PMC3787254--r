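test_that("rq_score matches the closed form and is monotone", {
  expect_equal(rq_score(rep(20, 7)), 20)          # E = 10^-2 exactly
  expect_equal(rq_score(c(10, 20)), -10 * log10(0.055), tolerance = 1e-10)
  expect_equal(rq_score(c(10, 20)), 12.59637, tolerance = 1e-5)
  expect_error(rq_score(integer(0)), "empty")
  set.seed(42)
  for (i in 1:20) {
    q <- sample(2:40, 10, replace = TRUE)
    j <- sample(10, 1)
    q2 <- q
    q2[j] <- q[j] + 1L
    expect_gt(rq_score(q2), rq_score(q))
  }
})

test_that("forward primer matching honors IUPAC codes and the window", {
  m <- match_forward_primer("GGAACCTTGGAACC", "GGAACC", 2)
  expect_true(m$found)
  expect_equal(m$start, 1)
  expect_equal(m$end, 6)
  expect_equal(m$diff, 0)
  # H in {A,C,T}, R in {A,G}: both cover the read bases at zero cost
  m2 <- match_forward_primer("GGAAAATTTTCCCC", "GGHAAR", 2)
  expect_equal(m2$diff, 0)
  expect_equal(m2$end, 6)
  # N in the read never matches the primer
  m3 <- match_forward_primer("GGNAAATTTT", "GGHAAR", 2)
  expect_equal(m3$diff, 1)
  # three substitutions exceed max_diff 2
  m4 <- match_forward_primer(paste0("TTTTTT", strrep("A", 30)),
                             "GGGGGG", 2)
  expect_false(m4$found)
  # degenerate-primer diff equals the best over all concrete expansions
  set.seed(11)
  for (i in 1:15) {
    primer <- paste(sample(c("A", "C", "G", "T", "R", "Y", "M", "W"), 7,
                           replace = TRUE), collapse = "")
    read <- random_seq(18)
    got <- match_forward_primer(read, primer, 7)
    want <- min(vapply(iupac_expansions(primer), function(p) {
      brute_semiglobal_dist(p, substr(read, 1, 2 * (nchar(p) + 7)))
    }, numeric(1)))
    expect_equal(got$diff, want)
  }
})

test_that("reverse primer matching uses the relaxed 3' heuristic", {
  p <- "ACGTACGTACGTA"     # plus-strand primer region in the read
  rp <- revcomp(p)         # what the researcher supplies
  # exact 6-base prefix flush with the read end: weight 6, accepted
  m <- match_reverse_primer(paste0(strrep("G", 20), substr(p, 1, 6)), rp, 1)
  expect_true(m$found)
  expect_true(m$partial)
  expect_equal(m$start, 21)
  # 12-base prefix, 1 difference: weight 11 - 6 = 5, rejected
  pre12 <- paste0(substr(p, 1, 4), "C", substr(p, 6, 12))
  m2 <- match_reverse_primer(paste0(strrep("G", 20), pre12), rp, 1)
  expect_false(m2$found)
  # 13-base prefix, 1 difference: weight 12 - 6 = 6, accepted
  pre13 <- paste0(substr(p, 1, 4), "C", substr(p, 6, 13))
  m3 <- match_reverse_primer(paste0(strrep("G", 20), pre13), rp, 1)
  expect_true(m3$found)
  expect_equal(m3$diff, 1)
  # but not when the user allows zero differences
  m4 <- match_reverse_primer(paste0(strrep("G", 20), pre13), rp, 0)
  expect_false(m4$found)
  # full primer present: matched without the heuristic
  m5 <- match_reverse_primer(paste0(strrep("G", 20), p, "TT"), rp, 1)
  expect_false(m5$partial)
  expect_equal(m5$start, 21)
})

make_tags <- function(...) {
  tt <- data.frame(tag = normalize_bases(c(...)),
                   sample = paste0("S", seq_along(c(...))),
                   stringsAsFactors = FALSE)
  class(tt) <- c("tag_table", "data.frame")
  tt
}

test_that("process_read applies the five filters in order", {
  set.seed(3)
  tags <- make_tags("ACGAGTGCGT")
  fwd <- "TGCGAYCCSAARGCBGACTC"
  rev <- "ATSGCCATCATYTCRCCGGA"
  primers <- primer_set(fwd, rev)
  insert <- random_seq(300)
  read <- paste0("ACGAGTGCGT", ampkit:::sample_iupac_expansion(fwd), insert,
                 revcomp(ampkit:::sample_iupac_expansion(rev)))
  r <- process_read("r1", read, NULL, tags, primers,
                    filter_config(min_length = 150))
  expect_true(r$passed)
  expect_equal(r$sample, "S1")
  expect_equal(r$bases, insert)

  # an uncalled base fails "n" before length or rq are even evaluated
  short_n <- paste0("ACGAGTGCGT", ampkit:::sample_iupac_expansion(fwd),
                    "ACGTN", revcomp(ampkit:::sample_iupac_expansion(rev)))
  rn <- process_read("r2", short_n, rep(5L, nchar(short_n)), tags, primers,
                     filter_config(min_length = 300, min_rq = 40))
  expect_false(rn$passed)
  expect_equal(rn$failed_filter, "n")

  # rq below the threshold fails "rq" (rq of all-Q19 bases is 19)
  rq_read <- paste0("ACGAGTGCGT", ampkit:::sample_iupac_expansion(fwd),
                    insert, revcomp(ampkit:::sample_iupac_expansion(rev)))
  rr <- process_read("r3", rq_read, rep(19L, nchar(rq_read)), tags, primers,
                     filter_config(min_length = 150, min_rq = 20))
  expect_false(rr$passed)
  expect_equal(rr$failed_filter, "rq")
  expect_equal(rr$rq, 19, tolerance = 1e-9)

  # unknown tag: NoTag, never filtered
  rt <- process_read("r4", paste0("TTTTTTTTTT", insert), NULL, tags, primers)
  expect_equal(rt$sample, "NoTag")
  expect_true(is.na(rt$failed_filter))
})

test_that("process_run audit counts partition the tag-matched reads", {
  mc <- build_mock_community(seed = 21)
  run <- simulate_run(mc, 80, error_model(sub_rate = 0.01, ins_rate = 0.004,
                                          del_rate = 0.004,
                                          hp_multiplier = 0.5),
                      seed = 22)
  tags <- make_tags(names(mc$tags))
  primers <- primer_set(mc$fwd_primer, mc$rev_primer)
  rep <- process_run(run$reads, tags, primers,
                     filter_config(min_length = 300), out_dir = NULL)
  s <- rep$summary
  expect_equal(s$matched_tag,
               s$passed + s$forward_primer + s$reverse_primer + s$n +
                 s$length + s$rq)
  # demultiplexing is order-independent
  set.seed(5)
  shuffled <- run$reads[sample(length(run$reads))]
  rep2 <- process_run(shuffled, tags, primers,
                      filter_config(min_length = 300), out_dir = NULL)
  expect_equal(rep2$summary, rep$summary)
  expect_setequal(rep2$passed$id, rep$passed$id)
})

test_that("keep_primer adds back exactly the trimmed primer bases", {
  mc <- build_mock_community(seed = 31)
  run <- simulate_run(mc, 30, error_model(sub_rate = 0, ins_rate = 0,
                                          del_rate = 0), seed = 32)
  tags <- make_tags(names(mc$tags))
  primers <- primer_set(mc$fwd_primer, mc$rev_primer)
  r1 <- process_run(run$reads, tags, primers,
                    filter_config(min_length = 100), out_dir = NULL)
  r2 <- process_run(run$reads, tags, primers,
                    filter_config(min_length = 100, keep_primer = TRUE),
                    out_dir = NULL)
  both <- intersect(r1$passed$id, r2$passed$id)
  len1 <- nchar(r1$passed$bases[match(both, r1$passed$id)])
  len2 <- nchar(r2$passed$bases[match(both, r2$passed$id)])
  expect_equal(len2 - len1,
               rep(nchar(mc$fwd_primer) + nchar(mc$rev_primer),
                   length(both)))
})

test_that("error-free simulated runs pass every filter", {
  mc <- build_mock_community(seed = 41)
  run <- simulate_run(mc, 50, error_model(sub_rate = 0, ins_rate = 0,
                                          del_rate = 0), seed = 42)
  tags <- make_tags(names(mc$tags))
  rep <- process_run(run$reads, tags,
                     primer_set(mc$fwd_primer, mc$rev_primer),
                     filter_config(min_length = 300), out_dir = NULL)
  expect_equal(rep$summary$passed, 50)
  # and an all-unknown-tag run lands entirely in NoTag
  other <- make_tags("GGGGGGGGGG")
  repn <- process_run(run$reads, other,
                      primer_set(mc$fwd_primer, mc$rev_primer),
                      filter_config(), out_dir = NULL)
  expect_equal(unique(repn$reads$sample), "NoTag")
  expect_equal(length(repn$passed), 0)
})

test_that("process_run writes the per-sample output tree", {
  mc <- build_mock_community(seed = 51)
  run <- simulate_run(mc, 20, error_model(sub_rate = 0, ins_rate = 0,
                                          del_rate = 0), seed = 52)
  tags <- make_tags(names(mc$tags))
  out <- file.path(tempfile(), "ip")
  rep <- process_run(run$reads, tags,
                     primer_set(mc$fwd_primer, mc$rev_primer),
                     filter_config(min_length = 300), out_dir = out)
  expect_true(file.exists(file.path(out, "summary.txt")))
  expect_true(file.exists(file.path(out, "S1", "trimmed.fasta")))
  expect_true(file.exists(file.path(out, "S1", "trimmed.qual")))
  expect_true(file.exists(file.path(out, "S1", "failed.txt")))
  expect_true(file.exists(file.path(out, "S1", "primers.txt")))
  back <- load_reads(file.path(out, "S1", "trimmed.fasta"),
                     qual_path = file.path(out, "S1", "trimmed.qual"))
  expect_setequal(back$id, rep$passed$id)
})
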