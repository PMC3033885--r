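#' F-distribution cumulative distribution function
#'
#' P(F <= x) for the F distribution with `v1` and `v2` degrees of freedom;
#' the building block of the variance-ratio gene informativeness score.
#'
#' @param x Non-negative quantile(s).
#' @param v1,v2 Positive degrees of freedom.
#' @return Probability in \[0, 1\].
#' @export
f_cdf <- function(x, v1, v2) {
  if (any(v1 <= 0) || any(v2 <= 0)) stop("degrees of freedom must be positive")
  if (any(x < 0)) stop("x must be non-negative")
  stats::pf(x, v1, v2)
}

# Single home of the informativeness orientation. The variance-ratio score of
# gene g for class k uses X = Var_all(g) / Var_k(g): a gene whose class-k
# values are tight relative to its overall spread has large X. The published
# description labels the score "1 - FCDF" but fixes the direction by prose
# (score close to 1 = most informative for the class); with X large, FCDF(X)
# -> 1, so the orientation implemented here is score = FCDF(X) — one minus
# the upper-tail p-value of the ratio. Changing the convention only requires
# editing this function.
fcdf_informativeness <- function(x_ratio, v1, v2) {
  f_cdf(x_ratio, v1, v2)
}

#' Variance-ratio (F-CDF) gene informativeness scores
#'
#' For gene g and class k the statistic X is the ratio of the gene's overall
#' sample variance to its within-class-k sample variance; the score is the
#' F CDF of X with (N - 1, n_k - 1) degrees of freedom (one minus the
#' upper-tail p-value). Scores near 1 mark genes whose expression is tight
#' within the class but variable across the dataset — informative markers for
#' that class. The per-gene summary is the maximum over classes.
#'
#' @param data An `expr_dataset`; every class needs >= 2 samples.
#' @param dof `"n_minus_1"` (default) uses sample-variance degrees of freedom
#'   (N - 1, n_k - 1); `"raw"` uses the plain counts (N, n_k).
#' @return An object of class `fcdf_score_table`: `scores` (genes x classes
#'   matrix), `summary` (per-gene max), `dof` (2 x classes matrix).
#' @export
fcdf_scores <- function(data, dof = c("n_minus_1", "raw")) {
  dof <- match.arg(dof)
  N <- n_samples(data)
  sizes <- table(factor(data$labels, levels = data$class_set))
  if (any(sizes < 2)) {
    stop("every class needs >= 2 samples for a within-class variance; class '",
         names(sizes)[which.min(sizes)], "' has ", min(sizes))
  }
  var_all <- apply(data$values, 2, stats::var)
  K <- length(data$class_set)
  scores <- matrix(NA_real_, nrow = n_genes(data), ncol = K,
                   dimnames = list(data$gene_ids, data$class_set))
  dofs <- matrix(NA_real_, nrow = 2, ncol = K,
                 dimnames = list(c("v1", "v2"), data$class_set))
  floor_var <- .Machine$double.eps * pmax(var_all, 1)
  for (k in seq_len(K)) {
    idx <- data$labels == data$class_set[k]
    var_k <- apply(data$values[idx, , drop = FALSE], 2, stats::var)
    if (any(var_k <= floor_var)) {
      warning(sum(var_k <= floor_var), " gene(s) with (near-)zero variance in class '",
              data$class_set[k], "'; variance floored")
      var_k <- pmax(var_k, floor_var)
    }
    x <- ifelse(var_all <= 0, 1, var_all / var_k)
    v1 <- if (dof == "n_minus_1") N - 1 else N
    v2 <- if (dof == "n_minus_1") sum(idx) - 1 else sum(idx)
    scores[, k] <- fcdf_informativeness(x, v1, v2)
    dofs[, k] <- c(v1, v2)
  }
  structure(list(scores = scores, summary = apply(scores, 1, max), dof = dofs),
            class = "fcdf_score_table")
}

#' @export
print.fcdf_score_table <- function(x, ...) {
  cat("<fcdf_score_table> ", nrow(x$scores), " genes x ", ncol(x$scores),
      " classes\n", sep = "")
  invisible(x)
}
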