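# Shared container for per-gene ranking scores.
gene_score_table <- function(method, scores, gene_ids) {
  ranking <- order(-scores, seq_along(scores), na.last = TRUE)
  structure(
    list(method = method, scores = as.numeric(scores),
         gene_ids = gene_ids, ranking = ranking),
    class = "gene_score_table"
  )
}

#' @export
print.gene_score_table <- function(x, ...) {
  cat("<gene_score_table> method=", x$method, ", ", length(x$scores),
      " genes\n", sep = "")
  top <- utils::head(x$ranking[!is.na(x$scores[x$ranking])], 5)
  if (length(top)) {
    cat("top:", paste0(x$gene_ids[top], " (",
                       formatC(x$scores[top], digits = 4, format = "g"), ")",
                       collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.gene_score_table <- function(x, ...) {
  data.frame(gene = x$ranking,
             gene_id = x$gene_ids[x$ranking],
             score = x$scores[x$ranking],
             rank = seq_along(x$ranking))
}

#' Rank genes by a filter method
#'
#' Scores every gene by `"infogain"` (information gain after MDL
#' discretization), `"relief"` (ReliefF) or `"cfs"` and returns the `top_n`
#' gene indices, scores descending with ties broken by ascending gene index.
#' For `"cfs"` the selected subset comes first (ordered by each gene's
#' individual class association), followed by the remaining genes by their
#' individual association, so that `top_n` larger than the CFS subset is
#' still meaningful.
#'
#' @param data An `expr_dataset`.
#' @param method One of `"infogain"`, `"relief"`, `"cfs"`.
#' @param top_n How many genes to return (default all).
#' @param ... Passed to the scoring function ([relief_scores()] arguments,
#'   `discretize=`/`bins=` for information gain).
#' @return List with `genes` (integer indices, length `top_n`), and `table`
#'   (the underlying `gene_score_table`).
#' @export
rank_genes <- function(data, method = c("infogain", "relief", "cfs"),
                       top_n = NULL, ...) {
  method <- match.arg(method)
  m <- n_genes(data)
  if (is.null(top_n)) top_n <- m
  if (top_n > m) stop("top_n (", top_n, ") exceeds gene count (", m, ")")
  tab <- switch(method,
    infogain = {
      sc <- vapply(seq_len(m), function(g)
        information_gain(data$values[, g], data$labels, ...), numeric(1))
      gene_score_table("infogain", sc, data$gene_ids)
    },
    relief = relief_scores(data, ...),
    cfs = {
      sel <- cfs_select(data)
      cache <- cfs_cache(data)
      rcf <- vapply(seq_len(m), function(g) cfs_rcf(cache, g), numeric(1))
      in_subset <- seq_len(m) %in% sel$subset
      ord <- order(!in_subset, -rcf, seq_len(m))
      out <- gene_score_table("cfs", rcf, data$gene_ids)
      out$ranking <- ord
      out$subset <- sel$subset
      out$merit <- sel$merit
      out
    }
  )
  list(genes = tab$ranking[seq_len(top_n)], table = tab)
}
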