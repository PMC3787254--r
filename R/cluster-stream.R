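#' Memory-constrained agglomerative clustering over a sorted edge stream
#'
#' Processes thin edges (single pairwise distances) in non-decreasing
#' order, maintaining thick edges (aggregates over all thin edges between
#' two clusters) and merging clusters at stepped distance cutoffs:
#'
#' * **single** linkage: two clusters merge at the first thin edge seen
#'   between them (the minimum, since the stream is sorted).
#' * **complete** linkage: a thick edge's weight is the largest thin edge
#'   seen so far; a pair merges when all `|A| * |B|` thin edges between
#'   the two clusters have been seen.
#' * **average** linkage: the running mean of seen thin edges, sandwiched
#'   between a lower bound (unseen edges scored at the last seen weight)
#'   and an upper bound (unseen edges scored at the largest pairwise
#'   distance recorded during distance computation). A pair merges once
#'   its thick edge has been seen in full and its exact mean is at most
#'   every other live thick edge's lower bound, so recorded merge heights
#'   are always exact.
#'
#' If more than `budget` thick edges would be live at once, the remaining
#' distances are scanned -- in one pass (`scan = "single"`) or in several
#' passes bounded by the budget (`scan = "multi"`) -- to fill out the
#' thick edges between the current clusters, and clustering resumes from
#' the completed aggregates. The resulting partitions are identical for
#' every budget; only the number of passes differs.
#'
#' @param stream an [edge_stream()].
#' @param method `"complete"`, `"average"` or `"single"`.
#' @param max_cutoff largest reported distance cutoff (default 0.5).
#' @param step cutoff step (default 0.01); levels are reported at every
#'   multiple of `step` from 0 to `max_cutoff`, each holding the
#'   partition in effect at that cutoff (merge height <= cutoff).
#' @param sample_map optional data.frame (`id`, `sample`) assigning each
#'   sequence to a sample; default: one sample named `"all"`.
#' @param budget maximum live thick edges before the exhaustion fallback.
#' @param scan exhaustion scan variant.
#' @param debug_bounds if TRUE (average linkage), assert after every
#'   processed edge that lower bound <= exact thick-edge mean <= upper
#'   bound, using `exact_dist`.
#' @param exact_dist full distance matrix for `debug_bounds`.
#' @return a [cluster_set()].
#' @export
cluster_stream <- function(stream, method = c("complete", "average", "single"),
                           max_cutoff = 0.5, step = 0.01, sample_map = NULL,
                           budget = Inf, scan = c("single", "multi"),
                           debug_bounds = FALSE, exact_dist = NULL) {
  method <- match.arg(method)
  scan <- match.arg(scan)
  n <- stream$n
  ids <- stream$ids
  edges <- stream$edges
  gmax <- stream$gmax
  eps <- 1e-12

  cl <- seq_len(n)              # cluster representative per sequence
  csize <- rep(1L, n)           # size per representative
  live <- rep(TRUE, n)
  CNT <- matrix(0, n, n)
  SUM <- matrix(0, n, n)
  MAX <- matrix(0, n, n)
  nte <- 0L
  merges <- list()

  record_merge <- function(a, b, h) {
    merges[[length(merges) + 1L]] <<- c(h = h, x = which(cl == a)[1],
                                        y = which(cl == b)[1])
    # the merged pair's own thick edge disappears
    if (CNT[min(a, b), max(a, b)] > 0) {
      CNT[min(a, b), max(a, b)] <<- 0
      SUM[min(a, b), max(a, b)] <<- 0
      MAX[min(a, b), max(a, b)] <<- 0
      nte <<- nte - 1L
    }
    # absorb b into a, combining thick edges
    cl[cl == b] <<- a
    csize[a] <<- csize[a] + csize[b]
    live[b] <<- FALSE
    others <- which(live & seq_len(n) != a)
    for (x in others) {
      had_a <- CNT[min(a, x), max(a, x)] > 0
      had_b <- CNT[min(b, x), max(b, x)] > 0
      if (had_b) {
        i1 <- min(a, x); j1 <- max(a, x)
        i2 <- min(b, x); j2 <- max(b, x)
        CNT[i1, j1] <<- CNT[i1, j1] + CNT[i2, j2]
        SUM[i1, j1] <<- SUM[i1, j1] + SUM[i2, j2]
        MAX[i1, j1] <<- max(MAX[i1, j1], MAX[i2, j2])
        CNT[i2, j2] <<- 0; SUM[i2, j2] <<- 0; MAX[i2, j2] <<- 0
        if (had_a) nte <<- nte - 1L  # two entries fused into one
        else if (!had_a) nte <<- nte  # entry moved, count unchanged
      }
    }
  }

  live_pairs <- function() {
    lv <- which(live)
    if (length(lv) < 2) return(NULL)
    cmb <- utils::combn(lv, 2L)
    data.frame(a = cmb[1, ], b = cmb[2, ])
  }

  pair_stats <- function(last_w) {
    lp <- live_pairs()
    if (is.null(lp)) return(NULL)
    idx <- cbind(lp$a, lp$b)
    lp$cnt <- CNT[idx]
    lp$sum <- SUM[idx]
    lp$max <- MAX[idx]
    lp$tot <- as.numeric(csize[lp$a]) * csize[lp$b]
    lp$complete <- lp$cnt >= lp$tot
    lp$mean <- ifelse(lp$cnt > 0, lp$sum / pmax(lp$cnt, 1), NA)
    lp$lower <- (lp$sum + (lp$tot - lp$cnt) * last_w) / lp$tot
    lp$upper <- (lp$sum + (lp$tot - lp$cnt) * gmax) / lp$tot
    lp
  }

  assert_bounds <- function(last_w) {
    lp <- pair_stats(last_w)
    if (is.null(lp)) return(invisible())
    for (r in which(lp$cnt > 0)) {
      mem_a <- which(cl == lp$a[r])
      mem_b <- which(cl == lp$b[r])
      tm <- mean(exact_dist[mem_a, mem_b])
      if (lp$lower[r] > tm + 1e-9 || lp$upper[r] < tm - 1e-9) {
        stop("average-linkage bound violated for clusters ", lp$a[r], "/",
             lp$b[r], ": lower ", lp$lower[r], " mean ", tm, " upper ",
             lp$upper[r], call. = FALSE)
      }
    }
  }

  # merge every pair whose linkage value is decided and minimal; returns
  # TRUE when a fully-seen thick edge remains unmerged (average linkage
  # only: its merge may become safe later, as the lower bounds tighten)
  try_merges <- function(last_w) {
    repeat {
      lp <- pair_stats(last_w)
      if (is.null(lp)) return(FALSE)
      cand <- lp[lp$complete & lp$cnt > 0, , drop = FALSE]
      if (nrow(cand) == 0) return(FALSE)
      if (method == "complete") {
        best <- cand[order(cand$max)[1], ]
        record_merge(best$a, best$b, best$max)
      } else { # average
        best <- cand[order(cand$sum / cand$tot)[1], ]
        h <- best$sum / best$tot
        others <- lp[!(lp$a == best$a & lp$b == best$b), , drop = FALSE]
        min_lower <- if (nrow(others) == 0) Inf else min(others$lower)
        if (h <= min_lower + eps) {
          record_merge(best$a, best$b, h)
        } else {
          return(TRUE)
        }
      }
    }
  }

  upsert <- function(a, b, w) {
    i <- min(a, b); j <- max(a, b)
    if (CNT[i, j] == 0) nte <<- nte + 1L
    CNT[i, j] <<- CNT[i, j] + 1
    SUM[i, j] <<- SUM[i, j] + w
    MAX[i, j] <<- w
    nte
  }

  prev_w <- -Inf
  k <- 1L
  exhausted <- FALSE
  pending <- FALSE  # a fully-seen thick edge is waiting for its bounds
  ei <- edges$i; ej <- edges$j; ew <- edges$w
  while (k <= nrow(edges)) {
    w <- ew[k]
    if (w < prev_w - eps) {
      stop("unsorted edge stream detected at edge ", k, " (", w, " after ",
           prev_w, ")", call. = FALSE)
    }
    prev_w <- w
    a <- cl[ei[k]]; b <- cl[ej[k]]
    if (a != b) {
      if (method == "single") {
        record_merge(a, b, w)
      } else {
        would_be_new <- CNT[min(a, b), max(a, b)] == 0
        if (would_be_new && nte + 1L > budget) { exhausted <- TRUE; break }
        upsert(a, b, w)
        if (CNT[min(a, b), max(a, b)] >=
            as.numeric(csize[a]) * csize[b]) pending <- TRUE
        if (pending) pending <- try_merges(w)
        if (debug_bounds && method == "average") assert_bounds(w)
      }
    }
    k <- k + 1L
  }

  if (exhausted) {
    rest <- data.frame(i = ei[seq.int(k, length(ew))],
                       j = ej[seq.int(k, length(ew))],
                       w = ew[seq.int(k, length(ew))])
    if (scan == "single") {
      # one pass: fill out thick edges between the frozen clusters
      for (r in seq_len(nrow(rest))) {
        a <- cl[rest$i[r]]; b <- cl[rest$j[r]]
        if (a != b) upsert(a, b, rest$w[r])
      }
    } else {
      # several passes, each completing at most `budget` thick edges
      repeat {
        lp <- pair_stats(gmax)
        todo <- lp[!lp$complete, , drop = FALSE]
        if (nrow(todo) == 0) break
        take <- todo[seq_len(min(nrow(todo), max(1, budget))), ]
        want <- paste(take$a, take$b)
        for (r in seq_len(nrow(rest))) {
          a <- cl[rest$i[r]]; b <- cl[rest$j[r]]
          if (a == b) next
          key <- paste(min(a, b), max(a, b))
          if (key %in% want) {
            # only count edges not yet aggregated for this pair: a pair in
            # `take` is incomplete, and pre-exhaustion aggregates already
            # include every edge before the freeze point, so scanning the
            # remainder exactly completes it
            upsert(a, b, rest$w[r])
          }
        }
      }
    }
    try_merges(gmax)
  } else if (method != "single") {
    # stream exhausted normally: every thick edge is complete (its lower
    # bound equals its exact mean), so this finishes the agglomeration
    # from exact aggregates
    try_merges(gmax)
  }

  build_cluster_set(merges, ids, sample_map,
                    cutoffs = seq(0, max_cutoff, by = step))
}

build_cluster_set <- function(merges, ids, sample_map, cutoffs) {
  n <- length(ids)
  samples_of <- if (is.null(sample_map)) {
    rep("all", n)
  } else {
    s <- sample_map$sample[match(ids, sample_map$id)]
    if (anyNA(s)) {
      stop("sample mapping missing id '", ids[which(is.na(s))[1]], "'",
           call. = FALSE)
    }
    s
  }
  roster <- unique(samples_of)
  sizes <- as.integer(table(factor(samples_of, levels = roster)))
  h <- vapply(merges, `[[`, numeric(1), "h")
  mx <- as.integer(vapply(merges, `[[`, numeric(1), "x"))
  my <- as.integer(vapply(merges, `[[`, numeric(1), "y"))
  levels <- lapply(cutoffs, function(cut) {
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    for (m in which(h <= cut + 1e-9)) {
      ra <- find(mx[m]); rb <- find(my[m])
      if (ra != rb) parent[rb] <- ra
    }
    comp <- vapply(seq_len(n), find, integer(1))
    groups <- split(seq_len(n), comp)
    groups <- groups[order(vapply(groups, min, integer(1)))]
    clusters <- lapply(seq_along(groups), function(g) {
      mem <- groups[[g]]
      bys <- split(ids[mem], factor(samples_of[mem], levels = roster))
      bys <- bys[lengths(bys) > 0]
      list(id = g - 1L, members = lapply(bys, as.character))
    })
    list(cutoff = cut, clusters = clusters)
  })
  cluster_set(roster, sizes, levels)
}

#' Cluster the sequences of a masked alignment
#'
#' Convenience wrapper: distances over comparable columns, sorted edge
#' stream, then [cluster_stream()].
#'
#' @inheritParams cluster_stream
#' @param maln a `masked_aln`.
#' @param min_overlap minimum compared positions per pair.
#' @param ... passed on to [cluster_stream()].
#' @return a [cluster_set()].
#' @export
cluster_sequences <- function(maln, method = "complete", max_cutoff = 0.5,
                              step = 0.01, sample_map = NULL,
                              min_overlap = 25L, ...) {
  if (length(maln$ids) == 1L) {
    # degenerate input: one sequence is one cluster at every level
    return(build_cluster_set(list(), maln$ids, sample_map,
                             cutoffs = seq(0, max_cutoff, by = step)))
  }
  es <- edge_stream(maln, min_overlap = min_overlap)
  cluster_stream(es, method = method, max_cutoff = max_cutoff, step = step,
                 sample_map = sample_map, ...)
}

#' Least-squares representative sequences
#'
#' For each cluster at the given cutoff, selects the member minimizing
#' the sum of squared distances to all other members; ties go to the
#' lexicographically smallest id. Singletons represent themselves.
#'
#' @param cs a [cluster_set()].
#' @param maln the `masked_aln` holding all member sequences.
#' @param cutoff clustering distance at which to pick representatives.
#' @param min_overlap minimum compared positions per pair.
#' @return data.frame `cluster`, `id`, `seq` (aligned).
#' @export
representative_sequences <- function(cs, maln, cutoff, min_overlap = 25L) {
  lv <- clust_level(cs, cutoff)
  m <- aln_char_matrix(maln)
  out <- lapply(lv$clusters, function(cl) {
    mem <- unlist(cl$members, use.names = FALSE)
    idx <- match(mem, maln$ids)
    if (anyNA(idx)) {
      stop("cluster member '", mem[which(is.na(idx))[1]],
           "' missing from the alignment", call. = FALSE)
    }
    if (length(idx) == 1) {
      pick <- idx
    } else {
      ssq <- vapply(seq_along(idx), function(u) {
        sum(vapply(seq_along(idx)[-u], function(v) {
          pair_dist(m[idx[u], ], m[idx[v], ], mem[u], mem[v],
                    min_overlap)^2
        }, numeric(1)))
      }, numeric(1))
      cand <- which(ssq <= min(ssq) + 1e-12)
      pick <- idx[cand[order(mem[cand])[1]]]
    }
    data.frame(cluster = cl$id, id = maln$ids[pick],
               seq = maln$seqs[pick], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write representative sequences as aligned FASTA
#'
#' The cluster id is recorded in each record's description.
#'
#' @param reps data.frame from [representative_sequences()].
#' @param path output file.
#' @return invisibly `path`.
#' @export
write_rep_seqs <- function(reps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in seq_len(nrow(reps))) {
    writeLines(c(sprintf(">%s cluster=%d", reps$id[r], reps$cluster[r]),
                 reps$seq[r]), con)
  }
  invisible(path)
}
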