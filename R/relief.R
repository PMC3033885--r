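#' ReliefF gene scores
#'
#' Multi-class ReliefF: for each probe sample, each gene's weight is decreased
#' by its (range-normalized, per-gene) distance to the k nearest same-class
#' neighbours ("hits") and increased by the class-prior-weighted distance to
#' the k nearest neighbours of every other class ("misses"). Genes whose
#' values separate classes while clustering within a class score high;
#' label-independent genes converge to 0.
#'
#' @param data An `expr_dataset`.
#' @param k_neighbors Number of hits/misses per probe. `NULL` (default) uses
#'   10 capped at the smallest class size minus one; an explicit value is a
#'   hard requirement and errors when some class is smaller than
#'   `k_neighbors + 1`.
#' @param n_probes Number of probe samples, or `"all"` (default). Sampling
#'   fewer probes is deterministic given `seed`.
#' @param seed Integer seed (only used when `n_probes < n`).
#' @return A `gene_score_table` (see [rank_genes()]) with scores in
#'   \[-1, 1\].
#' @export
relief_scores <- function(data, k_neighbors = NULL, n_probes = "all", seed = 1L) {
  n <- n_samples(data)
  m <- n_genes(data)
  cls <- class_index(data)
  sizes <- tabulate(cls)
  if (is.null(k_neighbors)) {
    k <- max(1L, min(10L, min(sizes) - 1L))
    if (min(sizes) < 2) stop("every class needs at least 2 members for ReliefF")
  } else {
    k <- as.integer(k_neighbors)
    if (any(sizes < k + 1)) {
      stop("every class needs at least k_neighbors + 1 = ", k + 1,
           " members; smallest class has ", min(sizes))
    }
  }
  # per-gene range normalization; constant genes contribute zero diff
  rng <- apply(data$values, 2, function(v) diff(range(v)))
  rng[rng <= 0] <- 1
  norm <- sweep(data$values, 2, rng, "/")

  if (identical(n_probes, "all") || n_probes >= n) {
    probes <- seq_len(n)
  } else {
    rs <- local_rng(seed)
    probes <- sort(rs$sample_int(n, as.integer(n_probes)))
  }
  priors <- sizes / n
  w <- numeric(m)
  dmat <- as.matrix(stats::dist(norm, method = "manhattan"))
  for (i in probes) {
    di <- dmat[i, ]
    di[i] <- Inf
    hits <- order(di + ifelse(cls == cls[i], 0, Inf))[seq_len(k)]
    diff_hit <- abs(sweep(norm[hits, , drop = FALSE], 2, norm[i, ], "-"))
    w <- w - colSums(diff_hit) / (length(probes) * k)
    for (c2 in seq_along(priors)) {
      if (c2 == cls[i]) next
      miss <- order(di + ifelse(cls == c2, 0, Inf))[seq_len(k)]
      diff_miss <- abs(sweep(norm[miss, , drop = FALSE], 2, norm[i, ], "-"))
      w <- w + (priors[c2] / (1 - priors[cls[i]])) *
        colSums(diff_miss) / (length(probes) * k)
    }
  }
  gene_score_table("relief", w, data$gene_ids)
}
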