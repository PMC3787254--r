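#' Analytic rarefaction curve
#'
#' Expected OTU richness after drawing `k` of the `N` sequences without
#' replacement: `E[S_k] = sum_i (1 - C(N - N_i, k) / C(N, k))`, evaluated
#' in log space so large counts do not overflow.
#'
#' @param counts non-negative integer OTU counts for one sample.
#' @param at subsampling depths to evaluate (default `1:N`).
#' @return data.frame `k`, `richness`.
#' @export
rarefaction <- function(counts, at = NULL) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (N < 1) stop("rarefaction of an empty sample", call. = FALSE)
  if (is.null(at)) at <- seq_len(N)
  rich <- vapply(at, function(k) {
    # log C(N - Ni, k) - log C(N, k); term is 0 when k > N - Ni
    p <- ifelse(k > N - counts, 0,
                exp(lchoose(N - counts, k) - lchoose(N, k)))
    sum(1 - p)
  }, numeric(1))
  data.frame(k = at, richness = rich)
}

#' Shannon diversity index
#'
#' `H = -sum p_i log(p_i)` with `p_i = N_i / N`; natural log by default.
#'
#' @param counts non-negative integer OTU counts.
#' @param base logarithm base (default `exp(1)`).
#' @return the index value.
#' @export
shannon <- function(counts, base = exp(1)) {
  counts <- counts[counts > 0]
  if (sum(counts) < 1) stop("Shannon index of an empty sample", call. = FALSE)
  p <- counts / sum(counts)
  -sum(p * log(p, base = base))
}

#' Chao1 richness estimator
#'
#' Bias-corrected form by default:
#' `S_obs + f1 (f1 - 1) / (2 (f2 + 1))`, which stays finite when no
#' doubletons are observed; the classic form
#' `S_obs + f1^2 / (2 f2)` is available for compatibility with tools
#' that expect it.
#'
#' @param counts non-negative integer OTU counts.
#' @param bias_corrected use the bias-corrected form (default TRUE).
#' @return the richness estimate (>= observed richness).
#' @export
chao1 <- function(counts, bias_corrected = TRUE) {
  counts <- counts[counts > 0]
  if (sum(counts) < 1) stop("Chao1 of an empty sample", call. = FALSE)
  s_obs <- length(counts)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else {
    if (f2 == 0) s_obs + f1 * (f1 - 1) / 2 else s_obs + f1^2 / (2 * f2)
  }
}

#' Chao abundance-corrected shared-OTU similarity
#'
#' Estimates the probabilities U and V that a sequence from sample 1
#' (resp. 2) belongs to a shared OTU, corrected for shared OTUs present
#' but unobserved in the other sample:
#' `U = sum_shared x_i/n + ((m-1)/m) (f_+1 / (2 f_+2)) *
#' sum_{shared, y_i = 1} x_i/n` (and symmetrically V), where `f_+1` and
#' `f_+2` count shared OTUs that are singletons resp. doubletons in the
#' other sample. When no doubletons are present the correction factor
#' denominator uses `max(2 f_+2, 2)`. U and V are capped at 1. The
#' abundance-based Jaccard index is `UV / (U + V - UV)` and Sorensen
#' `2UV / (U + V)`; both are 0 when the samples share no OTUs.
#'
#' @param x,y aligned count vectors for the two samples (same OTUs).
#' @return list with `U`, `V`, `jaccard`, `sorensen`.
#' @export
chao_shared_similarity <- function(x, y) {
  if (length(x) != length(y)) stop("count vectors differ in length",
                                   call. = FALSE)
  n <- sum(x)
  m <- sum(y)
  if (n < 1 || m < 1) stop("empty sample", call. = FALSE)
  shared <- x > 0 & y > 0
  if (!any(shared)) {
    return(list(U = 0, V = 0, jaccard = 0, sorensen = 0))
  }
  u_obs <- sum(x[shared]) / n
  v_obs <- sum(y[shared]) / m
  f_p1 <- sum(shared & y == 1)   # shared, singleton in sample 2
  f_p2 <- sum(shared & y == 2)
  f_1p <- sum(shared & x == 1)   # shared, singleton in sample 1
  f_2p <- sum(shared & x == 2)
  U <- u_obs + ((m - 1) / m) * (f_p1 / max(2 * f_p2, 2)) *
    sum(x[shared & y == 1]) / n
  V <- v_obs + ((n - 1) / n) * (f_1p / max(2 * f_2p, 2)) *
    sum(y[shared & x == 1]) / m
  U <- min(U, 1)
  V <- min(V, 1)
  list(U = U, V = V,
       jaccard = U * V / (U + V - U * V),
       sorensen = 2 * U * V / (U + V))
}

#' Sample similarity matrices for one clustering level
#'
#' @param otu matrix from [clust_to_otu_matrix()] (rows OTUs, columns
#'   samples).
#' @return list of symmetric matrices `jaccard` and `sorensen` with unit
#'   diagonal.
#' @export
beta_similarity <- function(otu) {
  s <- colnames(otu)
  J <- diag(1, length(s)); dimnames(J) <- list(s, s)
  S <- J
  if (length(s) >= 2) {
    for (a in seq_along(s)[-length(s)]) {
      for (b in seq.int(a + 1, length(s))) {
        cs <- chao_shared_similarity(otu[, a], otu[, b])
        J[a, b] <- J[b, a] <- cs$jaccard
        S[a, b] <- S[b, a] <- cs$sorensen
      }
    }
  }
  list(jaccard = J, sorensen = S)
}

#' UPGMA dendrogram of sample similarity
#'
#' Average-linkage clustering of the distance matrix `1 - similarity`;
#' node heights follow the ultrametric convention (tip-to-node depth is
#' half the linkage distance, so two samples with similarity 0.6 join at
#' height 0.2).
#'
#' @param sim symmetric similarity matrix, unit diagonal, >= 2 samples.
#' @return list with `phylo` (an [ape::as.phylo()] tree) and `newick`.
#' @export
upgma_dendrogram <- function(sim) {
  if (!is.matrix(sim) || nrow(sim) < 2) {
    stop("UPGMA requires two or more samples", call. = FALSE)
  }
  hc <- stats::hclust(stats::as.dist(1 - sim), method = "average")
  # ape::as.phylo.hclust already halves heights into ultrametric depths
  phy <- ape::as.phylo(hc)
  list(phylo = phy, newick = ape::write.tree(phy))
}

#' Alpha diversity table for every sample and cutoff of a cluster set
#'
#' @param cs a [cluster_set()].
#' @param cutoffs cutoffs to evaluate (default: all levels).
#' @return data.frame `cutoff`, `sample`, `s_obs`, `shannon`, `chao1`.
#' @export
alpha_diversity <- function(cs, cutoffs = NULL) {
  if (is.null(cutoffs)) cutoffs <- clust_cutoffs(cs)
  out <- lapply(cutoffs, function(cut) {
    otu <- clust_to_otu_matrix(cs, cut)
    do.call(rbind, lapply(colnames(otu), function(s) {
      v <- otu[, s]
      data.frame(cutoff = cut, sample = s, s_obs = sum(v > 0),
                 shannon = shannon(v), chao1 = chao1(v),
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, out)
}

#' Write diversity outputs for chosen cutoffs
#'
#' Per cutoff: rarefaction curves per sample, the alpha diversity table,
#' similarity matrices (one TSV per index), and UPGMA newick trees when
#' two or more samples are present.
#'
#' @param cs a [cluster_set()].
#' @param cutoffs cutoffs to report.
#' @param out_dir output directory (created).
#' @return invisibly `out_dir`.
#' @export
write_diversity <- function(cs, cutoffs, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(alpha_diversity(cs, cutoffs),
                     file.path(out_dir, "alpha_diversity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (cut in cutoffs) {
    tag <- sprintf("%.2f", cut)
    otu <- clust_to_otu_matrix(cs, cut)
    for (s in colnames(otu)) {
      rc <- rarefaction(otu[, s])
      utils::write.table(rc, file.path(out_dir,
                           sprintf("rarefaction_%s_%s.tsv", s, tag)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (ncol(otu) >= 2) {
      sims <- beta_similarity(otu)
      for (idx in names(sims)) {
        utils::write.table(sims[[idx]],
                           file.path(out_dir,
                                     sprintf("%s_%s.tsv", idx, tag)),
                           sep = "\t", quote = FALSE)
        tree <- upgma_dendrogram(sims[[idx]])
        writeLines(tree$newick,
                   file.path(out_dir, sprintf("upgma_%s_%s.nwk", idx, tag)))
      }
    }
  }
  invisible(out_dir)
}
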