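#' Sequencing error model for the read simulator
#'
#' Emulates 454-style pyrosequencing error profiles: independent per-base
#' substitutions, insertion/deletion rates that grow with homopolymer run
#' length (per-base indel odds are multiplied by
#' `1 + (run length - 1) * hp_multiplier`, a model choice emulating
#' flow-space miscalls), and per-base Phred qualities that decay along
#' the read with Gaussian noise.
#'
#' @param sub_rate substitution probability per base (default 0.002).
#' @param ins_rate insertion probability per base (default 0.0005).
#' @param del_rate deletion probability per base (default 0.0005).
#' @param hp_multiplier extra indel odds per homopolymer run-length unit
#'   (default 0.5; set 0 for run-length-independent indels).
#' @param mean_q mean Phred quality at the first cycle (default 33).
#' @param q_decay quality decay per cycle (default 0.02).
#' @param q_sd Gaussian quality noise (default 2).
#' @return an `error_model` list.
#' @export
error_model <- function(sub_rate = 0.002, ins_rate = 0.0005,
                        del_rate = 0.0005, hp_multiplier = 0.5,
                        mean_q = 33, q_decay = 0.02, q_sd = 2) {
  stopifnot(sub_rate >= 0, sub_rate < 1, ins_rate >= 0, ins_rate < 1,
            del_rate >= 0, del_rate < 1, hp_multiplier >= 0)
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate, hp_multiplier = hp_multiplier,
                 mean_q = mean_q, q_decay = q_decay, q_sd = q_sd),
            class = "error_model")
}

#' Build a defined (mock) community
#'
#' Generates `n_genes` gene templates by mutating a random ancestral core
#' at disjoint position sets, so every pair of genes differs at exactly
#' `divergence` of the core positions. Each gene carries a forward-primer
#' site and a reverse-primer site (reverse complement of the reverse
#' primer) into which a specified number of differences is written, as in
#' real defined communities where member genomes match the degenerate
#' amplification primers to varying degrees.
#'
#' @param n_genes number of member genes (>= 1).
#' @param length core template length between the primer sites.
#' @param divergence target pairwise core divergence, in (0, 0.5).
#' @param fwd_primer,rev_primer degenerate amplification primers (IUPAC).
#' @param primer_diff_profile integer vector (recycled over genes) of
#'   differences written into each gene's forward-primer site.
#' @param rev_diff_profile same for the reverse-primer site (default 0).
#' @param abundances relative template abundances (default uniform).
#' @param tags named character vector tag -> sample (default one MID,
#'   sample `"S1"`).
#' @param seed RNG seed; the same seed reproduces the community exactly.
#' @return a `mock_community`: genes (id, organism, core, full template,
#'   primer sites and their difference counts), primers, abundances,
#'   tags, seed.
#' @export
build_mock_community <- function(n_genes = 3, length = 321,
                                 divergence = 0.15,
                                 fwd_primer = "TGCGAYCCSAARGCBGACTC",
                                 rev_primer = "ATSGCCATCATYTCRCCGGA",
                                 primer_diff_profile = 0L,
                                 rev_diff_profile = 0L,
                                 abundances = NULL,
                                 tags = c(ACGAGTGCGT = "S1"),
                                 seed = 1L) {
  stopifnot(n_genes >= 1, divergence > 0, divergence < 0.5)
  per_gene <- round(divergence / 2 * length)
  if (per_gene * n_genes > length) {
    stop("divergence ", divergence, " infeasible for length ", length,
         " with ", n_genes, " genes", call. = FALSE)
  }
  if (is.null(abundances)) abundances <- rep(1 / n_genes, n_genes)
  stopifnot(length(abundances) == n_genes, all(abundances > 0))
  abundances <- abundances / sum(abundances)
  fwd_primer <- normalize_bases(fwd_primer)
  rev_primer <- normalize_bases(rev_primer)
  check_iupac(c(fwd_primer, rev_primer))
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ancestor <- sample(bases, length, replace = TRUE)
  fdiff <- rep_len(as.integer(primer_diff_profile), n_genes)
  rdiff <- rep_len(as.integer(rev_diff_profile), n_genes)
  # disjoint mutated position sets make every pairwise core distance
  # exactly 2 * per_gene / length = divergence
  pos_pool <- sample.int(length)
  genes <- lapply(seq_len(n_genes), function(g) {
    core <- ancestor
    if (per_gene > 0) {
      mut <- pos_pool[seq.int((g - 1L) * per_gene + 1L, g * per_gene)]
      core[mut] <- vapply(core[mut], function(b) {
        sample(setdiff(bases, b), 1L)
      }, character(1))
    }
    fsite <- mutate_primer_site(sample_iupac_expansion(fwd_primer),
                                fwd_primer, fdiff[g])
    rsite <- mutate_primer_site(sample_iupac_expansion(rev_primer),
                                rev_primer, rdiff[g])
    list(id = sprintf("gene%02d", g),
         organism = sprintf("organism_%02d", g),
         core = paste(core, collapse = ""),
         fwd_site = fsite, rev_site = rsite,
         template = paste0(fsite, paste(core, collapse = ""),
                           revcomp(rsite)),
         fwd_diff = fdiff[g], rev_diff = rdiff[g])
  })
  structure(list(genes = genes, fwd_primer = fwd_primer,
                 rev_primer = rev_primer, abundances = abundances,
                 tags = tags, seed = seed),
            class = "mock_community")
}

# write exactly `k` differences into a concrete primer site; each mutated
# position gets a base outside the degenerate primer's IUPAC set there,
# so the edit distance to the primer is exactly k
mutate_primer_site <- function(site, primer, k) {
  if (k == 0) return(site)
  ch <- strsplit(site, "", fixed = TRUE)[[1]]
  pb <- iupac_bits_of(primer)
  bases <- c("A", "C", "G", "T")
  bbits <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  eligible <- which(pb < 15L)  # an N position cannot host a difference
  if (k > length(eligible)) {
    stop("cannot write ", k, " differences into primer ", primer,
         call. = FALSE)
  }
  at <- sample(eligible, k)
  for (p in at) {
    opts <- bases[bitwAnd(bbits, pb[p]) == 0L]
    ch[p] <- sample(opts, 1L)
  }
  paste(ch, collapse = "")
}

#' @export
print.mock_community <- function(x, ...) {
  cat(sprintf("<mock_community> %d gene(s), %d sample tag(s), seed %d\n",
              length(x$genes), length(x$tags), x$seed))
  for (g in x$genes) {
    cat(sprintf("  %s (%s): %d bp, primer diffs fwd %d rev %d\n", g$id,
                g$organism, nchar(g$template), g$fwd_diff, g$rev_diff))
  }
  invisible(x)
}

#' Simulate a tagged amplicon sequencing run
#'
#' Each read is `tag + forward primer oligo + template core +
#' revcomp(reverse primer oligo)` -- the primer regions come from the
#' synthetic oligos (a fresh concrete expansion of the degenerate primer
#' per read), not from the genome, as in real amplicons. Substitution
#' and indel errors are injected downstream of the tag according to the
#' error model, and per-base qualities follow the decaying quality
#' model. The truth ledger records each read's source gene and injected
#' error counts.
#'
#' @param mc a [build_mock_community()] object.
#' @param n_reads total reads (split over tags in proportion to their
#'   order: reads are assigned to samples round-robin).
#' @param model an [error_model()].
#' @param read_length truncate reads to this length (default: full
#'   amplicon).
#' @param seed RNG seed.
#' @return list with `reads` (an [amp_reads] with qualities and sample
#'   labels) and `truth` (data.frame `id`, `gene`, `sample`, `n_sub`,
#'   `n_ins`, `n_del`).
#' @export
simulate_run <- function(mc, n_reads, model = error_model(),
                         read_length = NULL, seed = 1L) {
  set.seed(seed)
  tags <- names(mc$tags)
  samples <- unname(mc$tags)
  gene_idx <- sample.int(length(mc$genes), n_reads, replace = TRUE,
                         prob = mc$abundances)
  tag_idx <- rep_len(seq_along(tags), n_reads)
  ids <- sprintf("read%05d", seq_len(n_reads))
  bases_out <- character(n_reads)
  quals_out <- vector("list", n_reads)
  nsub <- integer(n_reads); nins <- integer(n_reads); ndel <- integer(n_reads)
  for (r in seq_len(n_reads)) {
    g <- mc$genes[[gene_idx[r]]]
    payload <- paste0(sample_iupac_expansion(mc$fwd_primer), g$core,
                      revcomp(sample_iupac_expansion(mc$rev_primer)))
    err <- inject_errors(payload, model)
    full <- paste0(tags[tag_idx[r]], err$seq)
    if (!is.null(read_length) && nchar(full) > read_length) {
      full <- substr(full, 1L, read_length)
    }
    bases_out[r] <- full
    n <- nchar(full)
    q <- round(model$mean_q - model$q_decay * seq_len(n) +
                 stats::rnorm(n, 0, model$q_sd))
    quals_out[[r]] <- pmax(2L, pmin(40L, as.integer(q)))
    nsub[r] <- err$n_sub; nins[r] <- err$n_ins; ndel[r] <- err$n_del
  }
  reads <- amp_reads(ids, bases_out, quals_out, samples[tag_idx])
  truth <- data.frame(id = ids,
                      gene = vapply(mc$genes, `[[`, character(1),
                                    "id")[gene_idx],
                      sample = samples[tag_idx],
                      n_sub = nsub, n_ins = nins, n_del = ndel,
                      stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}

# vectorized error injection over one sequence
inject_errors <- function(seq, model) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  bases <- c("A", "C", "G", "T")
  # homopolymer run length at each position (of the error-free template)
  r <- rle(ch)
  runlen <- rep(r$lengths, r$lengths)
  hp <- 1 + (runlen - 1) * model$hp_multiplier
  sub_at <- which(stats::runif(n) < model$sub_rate)
  for (p in sub_at) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
  ins_at <- which(stats::runif(n) < pmin(0.9, model$ins_rate * hp))
  del_at <- which(stats::runif(n) < pmin(0.9, model$del_rate * hp))
  out <- ch
  # build with insertions (duplicate the base: homopolymer over-call)
  if (length(ins_at) > 0) {
    ins_val <- ch[ins_at]
    pieces <- character(n)
    pieces[] <- out
    pieces[ins_at] <- paste0(pieces[ins_at], ins_val)
    out <- pieces
  }
  if (length(del_at) > 0) out[del_at] <- sub(".", "", out[del_at])
  list(seq = paste(out, collapse = ""),
       n_sub = length(sub_at), n_ins = length(ins_at),
       n_del = length(del_at))
}

#' Generate chimeric reads from a mock community
#'
#' Each chimera splices the cores of two distinct parent genes at a
#' random breakpoint, wrapped in tag and primer oligos like a normal
#' read; the truth table records both parents and the breakpoint.
#'
#' @param mc a [build_mock_community()] object (>= 2 genes).
#' @param n number of chimeras.
#' @param breakpoint_range fractional breakpoint window (default
#'   `c(0.3, 0.7)`).
#' @param seed RNG seed.
#' @return list with `reads` ([amp_reads]) and `truth` (data.frame `id`,
#'   `parent_a`, `parent_b`, `breakpoint`).
#' @export
make_chimeras <- function(mc, n, breakpoint_range = c(0.3, 0.7), seed = 1L) {
  if (length(mc$genes) < 2) stop("chimeras need at least two genes",
                                 call. = FALSE)
  set.seed(seed)
  ids <- character(n); seqs <- character(n)
  pa <- character(n); pb <- character(n); bp <- integer(n)
  tags <- names(mc$tags)
  for (r in seq_len(n)) {
    pick <- sample.int(length(mc$genes), 2L)
    ga <- mc$genes[[pick[1]]]; gb <- mc$genes[[pick[2]]]
    L <- nchar(ga$core)
    cut <- as.integer(round(stats::runif(1, breakpoint_range[1],
                                         breakpoint_range[2]) * L))
    core <- paste0(substr(ga$core, 1, cut), substr(gb$core, cut + 1L, L))
    ids[r] <- sprintf("chimera%03d", r)
    seqs[r] <- paste0(tags[1], sample_iupac_expansion(mc$fwd_primer), core,
                      revcomp(sample_iupac_expansion(mc$rev_primer)))
    pa[r] <- ga$id; pb[r] <- gb$id; bp[r] <- cut
  }
  list(reads = if (n == 0) amp_reads(character(0), character(0)) else
         amp_reads(ids, seqs, sample = unname(mc$tags)[1]),
       truth = data.frame(id = ids, parent_a = pa, parent_b = pb,
                          breakpoint = bp, stringsAsFactors = FALSE))
}
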