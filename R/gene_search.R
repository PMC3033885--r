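#' Drop redundant genes by pairwise correlation
#'
#' Scans a ranked gene list in order and drops any gene whose absolute
#' Pearson correlation with an already-kept gene exceeds `threshold`.
#' `threshold = 1` drops only exact duplicates (within numerical tolerance).
#'
#' @param genes Integer vector of gene indices, best first.
#' @param data An `expr_dataset`.
#' @param threshold Correlation ceiling in (0, 1\], default 0.9.
#' @return The filtered gene index vector, original order preserved.
#' @export
redundancy_filter <- function(genes, data, threshold = 0.9) {
  if (!length(genes)) stop("gene list must be nonempty")
  stopifnot(threshold > 0, threshold <= 1)
  cut <- min(threshold, 1 - 1e-10)
  kept <- integer(0)
  for (g in genes) {
    if (length(kept)) {
      r <- abs(suppressWarnings(
        stats::cor(data$values[, g], data$values[, kept, drop = FALSE])))
      r[is.na(r)] <- 0  # constant gene: undefined correlation, keep
      if (any(r > cut)) next
    }
    kept <- c(kept, g)
  }
  kept
}

#' Search for an optimal predictor gene set
#'
#' Iterative hill-climb driven by the F-CDF informativeness summary: at each
#' step the current set's least informative gene (lowest summary score) is
#' swapped for the most informative unused gene from the redundancy-filtered
#' candidate pool, and the new set is evaluated by hyper-box cross-validation.
#' Swapped-out genes retire from the pool, so the search stops after
#' `max_iter` swaps or when the pool is exhausted. The best set is the
#' recorded set with the highest accuracy (ties to the earliest iteration),
#' so the reported set is never worse than the initial one.
#'
#' @param data An `expr_dataset` (full gene space).
#' @param initial_set Integer gene indices to start from.
#' @param pool Ranked candidate gene indices (best first), e.g. from
#'   [rank_genes()].
#' @param max_iter Maximum number of swaps (default 20).
#' @param cv_spec List of [cross_validate()] arguments used to score a set;
#'   default stratified 10-fold, one repeat.
#' @param seed Seed for the fold plans.
#' @param corr_threshold Redundancy ceiling applied to the pool.
#' @param control [hbe_control()] passed to the classifier.
#' @return An object of class `search_trace`: `iterations` (data.frame with
#'   swapped_out, swapped_in, accuracy and the gene set per row), `sets`
#'   (list of integer vectors), `best_set`, `best_accuracy`.
#' @export
optimal_gene_set_search <- function(data, initial_set, pool, max_iter = 20,
                                    cv_spec = list(k = 10, repeats = 1),
                                    seed = 1L, corr_threshold = 0.9,
                                    control = hbe_control()) {
  initial_set <- as.integer(initial_set)
  if (anyDuplicated(initial_set)) stop("initial_set contains duplicates")
  scores <- fcdf_scores(data)$summary
  pool <- as.integer(pool)
  pool <- pool[order(-scores[pool], pool)]
  pool <- redundancy_filter(pool, data, corr_threshold)

  eval_set <- function(genes) {
    sub <- subset_dataset(data, genes = genes)
    args <- c(list(data = sub, seed = seed, control = control), cv_spec)
    do.call(cross_validate, args)$mean_accuracy
  }

  current <- initial_set
  sets <- list(current)
  rec <- data.frame(iteration = 0L, swapped_out = NA_integer_,
                    swapped_in = NA_integer_, accuracy = eval_set(current))
  unused <- setdiff(pool, current)
  retired <- integer(0)
  iter <- 0L
  while (iter < max_iter && length(unused)) {
    worst <- current[order(scores[current], current)][1]
    incoming <- unused[1]
    current <- sort(c(setdiff(current, worst), incoming))
    retired <- c(retired, worst)
    unused <- setdiff(unused, c(incoming, retired))
    iter <- iter + 1L
    sets[[iter + 1L]] <- current
    rec <- rbind(rec, data.frame(iteration = iter, swapped_out = worst,
                                 swapped_in = incoming,
                                 accuracy = eval_set(current)))
  }
  best_at <- which.max(rec$accuracy)  # first maximum = earliest iteration
  structure(list(iterations = rec, sets = sets,
                 best_set = sets[[best_at]],
                 best_accuracy = rec$accuracy[best_at]),
            class = "search_trace")
}

#' @export
print.search_trace <- function(x, ...) {
  cat("<search_trace> ", nrow(x$iterations) - 1, " swaps, best accuracy ",
      sprintf("%.4g", x$best_accuracy), "% with ",
      length(x$best_set), " genes\n", sep = "")
  invisible(x)
}
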