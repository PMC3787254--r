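---
title: "Models and methods behind ampkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ampkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampkit)
```

`ampkit` processes functional-gene amplicon reads from raw sequencer
output to OTU tables and diversity estimates. This vignette documents
the models and numerical choices behind each stage, what the synthetic
data generator does and does not emulate, and the design decisions that
were genuinely open.

## Read quality: the rQ score

A read's per-base Phred scores $Q_i$ encode error probabilities
$p_i = 10^{-Q_i/10}$. The read quality score is the Phred transform of
their *mean*:

$$\mathrm{rQ} = -10 \log_{10}\Big(\frac{1}{n}\sum_{i=1}^n 10^{-Q_i/10}\Big).$$

Because the mean is taken on the probability scale, a single Q=2 base in
an otherwise Q=40 read caps rQ near 20: rQ tracks the expected *number*
of errors, which is what downstream analyses care about. A read whose
bases are uniformly Q=q has rQ = q exactly (`rq_score(rep(20, 7))` is
20), which anchors the unit tests. The rQ filter (default threshold 20,
i.e. an expected error rate of 1%) is skipped, and noted in the run
summary, when the input carries no quality scores — it cannot be
evaluated, and silently failing every read would be worse.

## Initial processing: five filters, strictly ordered

Demultiplexing matches tags exactly at the extreme 5' end. Tag tables
are required to be prefix-free at load time, which makes the match
unambiguous; the underlying barcode designs guarantee this in practice,
and enforcing it early turns a silent mis-assignment into a loud error.

Filters run in a fixed order — forward primer, reverse primer, N,
length, rQ — and a failed read is attributed to exactly the first filter
it failed, so per-filter counts partition the tag-matched reads. That
partition property is asserted in the tests.

*Primer differences* are unit-cost edit distance (substitutions and
indels), computed by a semiglobal alignment in which the primer must be
consumed in full. A degenerate position in the primer matches, at zero
cost, any base it encodes; an N in the read matches nothing. The primer
search is windowed: after the tag, the forward primer must begin within
`primer length + max_diff` bases, bounding cost and reflecting amplicon
structure (the window is a package choice; nothing forces one, but an
unwindowed search could "find" a primer mid-read).

*Reverse primer.* Sequencers frequently stop inside the reverse primer,
so after a full-primer search fails, a relaxed heuristic scans for a
primer *prefix* terminating at the read's final base, scoring +1 per
match and −6 per difference and accepting at weight ≥ 6. Consequently a
clean 6-base prefix is enough; a 12-base prefix tolerates no error
(11 − 6 = 5 < 6) while a 13-base prefix tolerates one (12 − 6 = 6). No
differences are accepted when the user demands zero. The supplied
reverse primer is reverse-complemented before searching, which amplicon
geometry forces: reads run 5'→3' into the complement of the reverse
primer. Both trims remove the primer regions unless `keep_primer`; the
length filter therefore measures the biological insert.

## Defined-community error profiling

Each read is globally aligned (Needleman–Wunsch) against every
reference; the highest-scoring reference is taken as the source
organism, ties going to the first listed and flagged ambiguous. The
original tool's scoring constants are unpublished, so the package fixes
match +1, mismatch −1, gap −2 (linear). Two properties motivated the
choice: a substitution is never re-explained as an indel pair
(−1 > −4), and the scheme is simple enough to verify against exhaustive
enumeration of all global alignments for short strings, plus an
independent dynamic-programming oracle for long ones — both are in the
test suite. Error *rates* on mock data are insensitive to reasonable
scoring choices; error *positions* can shift within a homopolymer run,
which is why positions are canonicalized (below).

After alignment, gap columns are slid to the 3'-most equivalent position
of their homopolymer run. Each slide swaps a gap with an identical
adjacent base and is score-neutral in an optimal alignment, so
optimality is preserved while making "the inserted base" well defined:
for `AACGT` vs `ACGT` the insertion is the *second* A, with expected
homopolymer length 1 and observed length 2. Indel records carry the
expected (reference) and observed (read) run lengths of the indel base,
1-based alignment/read/reference positions, and the Q score of the extra
base for insertions — the signature outputs needed to diagnose
pyrosequencing homopolymer miscalls.

The summary reports errors per aligned reference base, the error-free
read fraction, the indel read fraction, per-reference counts, and rates
per integer rQ bin (floor of rQ, matching how per-score behavior is
usually plotted). Re-summarizing supports exclusion lists (vetted
chimeras/contaminants), restriction by reverse-primer difference count,
and rQ thresholds, so parameter exploration does not recompute
alignments. `flag_outliers` lists reads at ≥ 10% distance from their
best reference (per-base differences over aligned reference length) for
external chimera vetting; error-free reads are never flagged, so a zero
threshold flags exactly the reads with at least one error.

## Streaming clustering: thin and thick edges

Pairwise distance is the uncorrected mismatch fraction over comparable
alignment columns (the `#=GC_RF` match states), with pairwise deletion:
columns where either record has a gap are excluded from numerator and
denominator. A minimum-overlap guard (default 25 compared positions)
turns near-disjoint pairs into a hard error instead of a meaningless
distance. Characters compare case-insensitively; IUPAC codes match when
their base sets intersect.

All $n(n-1)/2$ distances are sorted ascending (spilling to disk in
chunks when an in-memory budget is exceeded; chunk count is clamped at
64 so the merge never exhausts open connections) with ties broken by
index pair, making every downstream merge deterministic. Clustering
consumes this stream:

* **single**: merge on the first edge between two clusters — sorted
  order makes it the minimum.
* **complete**: a thick edge (cluster pair) tracks the max of its seen
  thin edges and merges when all $|A||B|$ of them have been seen; in a
  sorted stream the first pair to complete is the one with the smallest
  max, reproducing naive complete linkage.
* **average**: a thick edge tracks count and sum. Its exact mean is
  bracketed by substituting, for the unseen edges, the last seen weight
  (lower bound — everything still to come is at least that) or the
  globally largest distance recorded during distance computation (upper
  bound). A pair merges when it has been seen in full *and* its exact
  mean is at most every other live pair's lower bound.

The second condition is deliberately stricter than bounds alone, which
can prove a merge safe while some of the pair's edges are still unseen —
at that point the merge *height* is known only as an interval. Deferring
until the pair is fully seen keeps every recorded height exact, which the
reported partitions-at-cutoff require; the bounds still gate the merge
and are asserted (lower ≤ exact mean ≤ upper at every processed edge) in
a debug mode. If the number of live thick edges exceeds the memory
budget, the remaining distances are scanned — in one pass, or in several
budget-bounded passes (`scan = "multi"`) — to fill out the thick edges
between the current clusters, after which every pair is fully seen and
the agglomeration finishes from exact aggregates. Results are identical
for every budget; only the pass count differs (asserted in tests).

Levels are reported at every multiple of `step` up to `max_cutoff`, each
holding the partition of merges with height ≤ cutoff; merges between
step values therefore appear at the next step, and partitions coarsen
monotonically. Cluster representatives minimize the sum of squared
distances to their co-members (least squares), with ties broken to the
lexicographically smallest id.

The whole stack is validated against `stats::hclust` partitions on
random all-distinct distance matrices up to n = 50; ties among distances
are excluded from the oracle comparison because tied agglomerative
merges are order-dependent in any implementation.

## Diversity estimators

Rarefaction is analytic,
$E[S_k] = \sum_i \big(1 - \binom{N-N_i}{k}/\binom{N}{k}\big)$,
evaluated via `lchoose` in log space, and cross-checked against
Monte-Carlo subsampling. Shannon uses natural log (a `base` argument is
provided). Chao1 defaults to the bias-corrected form
$S_{obs} + f_1(f_1-1)/(2(f_2+1))$, finite when $f_2 = 0$; the classic
form is a flag for compatibility with estimateS-style exports. The
abundance-based Jaccard and Sørensen indices use the Chao-corrected
shared-abundance estimators U and V, with the standard
$\max(2f_{+2}, 2)$ denominator guard when no doubletons exist, U and V
capped at 1, and both indices defined as 0 for disjoint samples. UPGMA
dendrograms cluster $1 - $ similarity with average linkage; newick
heights follow the ultrametric convention (tip-to-node depth is half the
linkage distance, so two samples at similarity 0.6 join at height 0.2).
`ape` performs that halving in `as.phylo.hclust`, so heights are passed
through unmodified.

## Probe matching

Probe search uses the same semiglobal alignment as primer matching:
query fully consumed, free target ends, unit costs. With ambiguity
enabled, characters match when their IUPAC sets intersect — so `R`
matches `A` at distance 0 with ambiguity on and distance 1 with it off.
Only the best hit per target is reported (lowest distance, then
leftmost), and zero distance with ambiguity off reduces to exact
substring search. Reverse-primer mode searches the reverse complement of
the query, which is provably the same as forward search on
reverse-complemented targets (and is tested as such). End-gap treatment
is a package decision: free target ends match primer-site semantics,
where flanking target sequence is not a penalty.

## The simulator: a stated world

`build_mock_community` mutates a random ancestral core at *disjoint*
position sets so that every pairwise core distance is exactly the
requested divergence (default 0.15 — comfortably above species-level
cutoffs and below saturation); primer sites receive an exact number of
differences each, written only at positions where the degenerate primer
is informative. Reads are `tag + forward oligo + core + revcomp(reverse
oligo)` with the primer regions drawn as fresh concrete expansions of
the degenerate primers — as in real amplicons, whose primer regions
derive from the synthetic oligos, not the genome. Defaults (321 bp core,
20-mer degenerate primers, one 10-mer MID) mirror a typical
nitrogenase-reductase amplicon design.

The error model injects independent substitutions (default 0.002/base)
and insertions/deletions (0.0005 each) whose odds grow with homopolymer
run length (`1 + (L-1) × 0.5` by default), emulating pyrosequencing
flow-space miscalls; qualities decay linearly with cycle plus Gaussian
noise. It does *not* emulate flowgrams, chimera formation during PCR
(that is `make_chimeras`, which splices two cores at a controlled
breakpoint), PCR abundance bias beyond the fixed multinomial, or
quality/error correlation. A green parameter-recovery test therefore
establishes that the measurement machinery is unbiased for independent
errors at realistic rates — not that it reproduces every 454 artifact.
Note that with a nonzero homopolymer multiplier the *realized* indel
rate exceeds the nominal per-base rate by construction; rate-recovery
tests set the multiplier to 0 because they test recovery of a stated
binomial rate, and this is a property of the stated world, not a tuning.

All generators are seeded and reproducible; every acceptance simulation
fixes its seed.

## Numerical and degenerate-input choices

* Merge-height comparisons use a 1e-9 tolerance when slotting merges
  into cutoff levels, so a merge at exactly 0.03 appears at the 0.03
  level despite binary representation.
* An unsorted edge stream is a hard error (it would silently corrupt
  every linkage rule).
* A single-sequence clustering input yields one cluster at every level
  without touching the stream machinery.
* Empty quality vectors make rQ undefined (error), not zero.
* `.clust` cutoffs are written with `%.10g`, which round-trips every
  step-grid value exactly.

## Known limitations

* FASTQ parsing is strict four-line; SFF and BIOM are out of scope
  (convert upstream / downstream).
* Alignments are consumed, not produced: clustering expects
  profile-aligned FASTA with a `#=GC_RF` mask row from an external
  aligner, or equal-length pre-trimmed reads via
  `as_masked_alignment()`.
* Chimera detection is an external hook; the pipeline validates the
  hook's output but ships no detector.
* The streaming clustering stores thick edges in dense n×n matrices —
  faithful to the algorithm's accounting but not to its absolute memory
  footprint at very large n.
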