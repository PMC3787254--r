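test_that("global alignment score equals exhaustive enumeration (len <= 6)", {
  set.seed(17)
  for (i in 1:150) {
    a <- random_seq(sample(1:6, 1))
    b <- random_seq(sample(1:6, 1))
    expect_equal(global_align(a, b)$score, enum_nw_score(a, b),
                 info = paste(a, b))
  }
})

test_that("global alignment score agrees with Biostrings on long pairs", {
  skip_if_not_installed("Biostrings")
  set.seed(19)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  for (i in 1:10) {
    a <- random_seq(sample(80:200, 1))
    b <- random_seq(sample(80:200, 1))
    want <- Biostrings::pairwiseAlignment(
      a, b, type = "global", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = 2, scoreOnly = TRUE)
    expect_equal(global_align(a, b)$score, want)
  }
})

test_that("alignments recover their inputs and obey column conservation", {
  set.seed(23)
  for (i in 1:25) {
    a <- random_seq(sample(5:60, 1))
    b <- random_seq(sample(5:60, 1))
    al <- global_align(a, b)
    expect_equal(gsub("-", "", al$read_aln), a)
    expect_equal(gsub("-", "", al$ref_aln), b)
    tab <- tabulate_errors(al)
    ra <- strsplit(al$read_aln, "")[[1]]
    rb <- strsplit(al$ref_aln, "")[[1]]
    n_match <- sum(ra == rb & ra != "-")
    expect_equal(n_match + nrow(tab$substitutions) + nrow(tab$indels),
                 nchar(al$read_aln))
  }
})

test_that("error typing matches hand-computed homopolymer context", {
  al <- global_align("ACGT", "ACGT")
  tab <- tabulate_errors(al)
  expect_equal(nrow(tab$substitutions), 0)
  expect_equal(nrow(tab$indels), 0)

  ins <- tabulate_errors(global_align("AACGT", "ACGT"),
                         quals = c(30L, 31L, 32L, 33L, 34L))$indels
  expect_equal(ins$type, "insertion")
  expect_equal(ins$base, "A")
  expect_equal(ins$expected_len, 1L)
  expect_equal(ins$observed_len, 2L)
  expect_equal(ins$qual, 31L)  # the 3'-most A of the run is the extra base

  del <- tabulate_errors(global_align("AAT", "AAAT"))$indels
  expect_equal(del$type, "deletion")
  expect_equal(del$base, "A")
  expect_equal(del$expected_len, 3L)
  expect_equal(del$observed_len, 2L)

  sub <- tabulate_errors(global_align("ACTT", "ACGT"))$substitutions
  expect_equal(sub$aln_pos, 3L)
  expect_equal(sub$expected, "G")
  expect_equal(sub$observed, "T")
})

test_that("best-reference assignment scores and tie-breaks correctly", {
  set.seed(29)
  refs <- c(R1 = random_seq(60), R2 = random_seq(60), R3 = random_seq(60))
  al <- assign_best_reference(refs[["R2"]], refs)
  expect_equal(al$ref_id, "R2")
  expect_equal(al$score, 60)
  # one substitution from R1, far from the others
  r1 <- refs[["R1"]]
  new_base <- setdiff(c("A", "C", "G", "T"), substr(r1, 31, 31))[1]
  read <- paste0(substr(r1, 1, 30), new_base, substr(r1, 32, 60))
  al1 <- assign_best_reference(read, refs)
  expect_equal(al1$ref_id, "R1")
  expect_false(al1$ambiguous)
  # two identical references tie: first listed wins, flagged ambiguous
  refs2 <- c(A = refs[["R1"]], B = refs[["R1"]])
  al2 <- assign_best_reference(refs[["R1"]], refs2)
  expect_equal(al2$ref_id, "A")
  expect_true(al2$ambiguous)
  expect_error(assign_best_reference("ACGT", character(0)), "empty")
})

test_that("summaries reproduce rates and support exact subsetting", {
  mc <- build_mock_community(seed = 61)
  run <- simulate_run(mc, 40, error_model(sub_rate = 0.01,
                                          ins_rate = 0.002,
                                          del_rate = 0.002,
                                          hp_multiplier = 0), seed = 62)
  refs <- stats::setNames(
    vapply(mc$genes, `[[`, character(1), "template"),
    vapply(mc$genes, `[[`, character(1), "id"))
  # compare untrimmed reads (minus tag) to full templates
  tl <- nchar(names(mc$tags)[1])
  reads <- amp_reads(run$reads$id,
                     substring(run$reads$bases, tl + 1),
                     lapply(run$reads$quals, function(q) q[-seq_len(tl)]),
                     run$reads$sample)
  ea <- error_analysis(reads, refs)
  s <- summarize_errors(ea)
  # summary rate equals the rate recomputed from the raw records
  nerr <- nrow(ea$substitutions) + nrow(ea$indels)
  expect_equal(s$error_rate, nerr / s$aligned_ref_bases)
  expect_equal(s$total_substitutions, nrow(ea$substitutions))
  # excluding ids shrinks per-reference counts by exactly their membership
  drop <- ea$per_read$id[1:5]
  s2 <- summarize_errors(ea, exclude_ids = drop)
  expect_equal(s2$n_reads, s$n_reads - 5)
  dropped_refs <- table(factor(ea$per_read$ref_id[1:5],
                               levels = names(s$reads_per_reference)))
  expect_equal(as.vector(s$reads_per_reference) - as.vector(dropped_refs),
               as.vector(s2$reads_per_reference))
  # rQ bins are floors of per-read rQ
  expect_true(all(s$rq_bins$rq_bin == floor(s$rq_bins$rq_bin)))
  expect_equal(sum(s$rq_bins$reads), s$n_reads)
  # min_rq filtering
  thr <- stats::median(ea$per_read$rq)
  s3 <- summarize_errors(ea, min_rq = thr)
  expect_equal(s3$n_reads, sum(ea$per_read$rq >= thr))
})

test_that("rev-diff subsetting uses the audit counts", {
  per <- data.frame(id = c("a", "b", "c"), ref_id = "R", score = 1,
                    ambiguous = FALSE, aln_len = 10, ref_bases = 10,
                    n_sub = c(1, 0, 2), n_ins = 0, n_del = 0,
                    rq = c(20, 25, 30))
  ea <- structure(list(per_read = per,
                       substitutions = NULL, indels = NULL,
                       alignments = list()), class = "error_analysis")
  rd <- c(a = 0L, b = 1L, c = 2L)
  s <- summarize_errors(ea, rev_diffs = rd, rev_diff = c(1, 2))
  expect_equal(s$n_reads, 2)
  expect_equal(s$total_substitutions, 2)
  expect_error(summarize_errors(ea, rev_diff = 1), "rev_diffs")
})

test_that("outlier flagging follows the distance threshold", {
  # 2 differences over 321 aligned bases is 0.6%: kept
  set.seed(67)
  ref <- c(REF = random_seq(321))
  read <- ref[[1]]
  substr(read, 10, 10) <- if (substr(read, 10, 10) == "A") "C" else "A"
  substr(read, 200, 200) <- if (substr(read, 200, 200) == "G") "T" else "G"
  ea <- error_analysis(amp_reads("r1", read), ref)
  expect_length(flag_outliers(ea, 0.10), 0)
  # threshold 0 flags every read with at least one error, nothing else
  ea2 <- error_analysis(amp_reads(c("ok", "bad"), c(ref[[1]], read)), ref)
  expect_equal(flag_outliers(ea2, 0), "bad")
})

test_that("chimeras between divergent references are flagged", {
  mc <- build_mock_community(n_genes = 2, divergence = 0.30, seed = 71)
  chim <- make_chimeras(mc, 3, breakpoint_range = c(0.45, 0.55), seed = 72)
  refs <- stats::setNames(
    vapply(mc$genes, `[[`, character(1), "core"),
    vapply(mc$genes, `[[`, character(1), "id"))
  # strip tag and primers to compare cores
  core <- substring(chim$reads$bases,
                    nchar(names(mc$tags)[1]) + nchar(mc$fwd_primer) + 1)
  core <- substr(core, 1, nchar(core) - nchar(mc$rev_primer))
  ea <- error_analysis(amp_reads(chim$reads$id, core), refs)
  expect_setequal(flag_outliers(ea, 0.10), chim$reads$id)
})
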