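# Correlation-based feature selection. Both association terms (feature-class
# and feature-feature) are symmetrical uncertainty computed on MDL-discretized
# expression values, keeping them on [0, 1].

# Cache of discretized features and pairwise SU values, shared across the
# best-first search.
cfs_cache <- function(data) {
  env <- new.env(parent = emptyenv())
  env$data <- data
  env$disc <- vector("list", n_genes(data))
  env$rcf <- rep(NA_real_, n_genes(data))
  env$rff <- new.env(parent = emptyenv())
  env
}

cfs_disc <- function(cache, g) {
  if (is.null(cache$disc[[g]])) {
    v <- cache$data$values[, g]
    cache$disc[[g]] <- apply_cuts(v, discretize_mdl(v, cache$data$labels))
  }
  cache$disc[[g]]
}

cfs_rcf <- function(cache, g) {
  if (is.na(cache$rcf[g])) {
    cache$rcf[g] <- symmetrical_uncertainty(cfs_disc(cache, g), cache$data$labels)
  }
  cache$rcf[g]
}

cfs_rff <- function(cache, g1, g2) {
  key <- paste0(min(g1, g2), ":", max(g1, g2))
  val <- cache$rff[[key]]
  if (is.null(val)) {
    val <- symmetrical_uncertainty(cfs_disc(cache, g1), cfs_disc(cache, g2))
    cache$rff[[key]] <- val
  }
  val
}

cfs_merit_cached <- function(cache, subset) {
  k <- length(subset)
  rcf <- mean(vapply(subset, function(g) cfs_rcf(cache, g), numeric(1)))
  if (k == 1) return(rcf)
  pairs <- utils::combn(subset, 2)
  rff <- mean(apply(pairs, 2, function(p) cfs_rff(cache, p[1], p[2])))
  k * rcf / sqrt(k + k * (k - 1) * rff)
}

#' CFS merit of a gene subset
#'
#' Merit = k * mean(r_cf) / sqrt(k + k (k - 1) * mean(r_ff)) for a subset of k
#' genes, where r_cf is the gene-class association and r_ff the pairwise
#' gene-gene association (both symmetrical uncertainty on MDL-discretized
#' values). High merit means the subset predicts the class while carrying
#' little internal redundancy.
#'
#' @param subset Integer vector of gene indices (nonempty).
#' @param data An `expr_dataset`.
#' @return The merit value.
#' @export
cfs_merit <- function(subset, data) {
  if (!length(subset)) stop("subset must be nonempty")
  cfs_merit_cached(cfs_cache(data), as.integer(subset))
}

#' Select a gene subset by CFS with best-first search
#'
#' Greedy forward best-first search over subsets maximizing [cfs_merit()],
#' terminating after 5 consecutive expansions that fail to improve the best
#' merit found.
#'
#' @param data An `expr_dataset` with at least one gene.
#' @param max_stale Consecutive non-improving expansions tolerated.
#' @return A `gene_score_table` with `method = "cfs"`; `scores` holds each
#'   gene's individual class association (r_cf) for selected genes and `NA`
#'   elsewhere, `subset` the selected gene indices and `merit` the subset
#'   merit.
#' @export
cfs_select <- function(data, max_stale = 5L) {
  m <- n_genes(data)
  stopifnot(m >= 1)
  cache <- cfs_cache(data)
  # open list of frontier subsets (as sorted integer vectors) with merits
  open_sets <- list(integer(0))
  open_merit <- -Inf
  visited <- new.env(parent = emptyenv())
  best_set <- integer(0)
  best_merit <- -Inf
  stale <- 0L
  while (length(open_sets) && stale < max_stale) {
    at <- which.max(open_merit)
    node <- open_sets[[at]]
    open_sets <- open_sets[-at]
    open_merit <- open_merit[-at]
    improved <- FALSE
    for (g in setdiff(seq_len(m), node)) {
      child <- sort(c(node, g))
      key <- paste(child, collapse = ",")
      if (!is.null(visited[[key]])) next
      visited[[key]] <- TRUE
      merit <- cfs_merit_cached(cache, child)
      open_sets <- c(open_sets, list(child))
      open_merit <- c(open_merit, merit)
      if (merit > best_merit + 1e-12) {
        best_merit <- merit
        best_set <- child
        improved <- TRUE
      }
    }
    stale <- if (improved) 0L else stale + 1L
  }
  scores <- rep(NA_real_, m)
  scores[best_set] <- vapply(best_set, function(g) cfs_rcf(cache, g), numeric(1))
  out <- gene_score_table("cfs", scores, data$gene_ids)
  out$subset <- best_set
  out$merit <- best_merit
  out
}
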