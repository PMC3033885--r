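#' Shannon entropy of a label vector (bits)
#'
#' H(Y) = -sum p(c) log2 p(c) over the observed classes; the uncertainty a
#' gene must reduce to be informative about the tumor type.
#'
#' @param labels Vector of class identifiers.
#' @return Entropy in bits, between 0 and log2(number of classes).
#' @export
entropy <- function(labels) {
  if (!length(labels)) stop("labels must be nonempty")
  p <- tabulate(as.integer(factor(labels)))
  p <- p[p > 0] / length(labels)
  -sum(p * log2(p))
}

entropy_counts <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts / n
  -sum(p * log2(p))
}

#' Mutual information between two discrete vectors (bits)
#'
#' I(X;Y) = H(X) + H(Y) - H(X,Y), computed from the joint contingency table.
#' This is the quantity information gain reduces to once a continuous gene has
#' been discretized.
#'
#' @param x,y Discrete vectors of equal length (any type coercible to factor).
#' @return Mutual information in bits (non-negative up to rounding).
#' @export
mutual_information <- function(x, y) {
  stopifnot(length(x) == length(y))
  joint <- table(x, y)
  mutual_information_table(joint)
}

#' @rdname mutual_information
#' @param joint A contingency table / matrix of joint counts (x in rows,
#'   y in columns).
#' @export
mutual_information_table <- function(joint) {
  joint <- as.matrix(joint)
  entropy_counts(rowSums(joint)) + entropy_counts(colSums(joint)) -
    entropy_counts(as.vector(joint))
}

#' Supervised discretization by recursive MDL partitioning
#'
#' Fayyad-Irani style entropy minimization: recursively place the binary cut
#' that minimizes class entropy, accepting a cut only if its information gain
#' passes the minimum-description-length criterion. Continuous expression
#' values must be discretized before entropy-based gene scoring; an empty cut
#' list means the gene collapses to a single bin (no usable class signal).
#'
#' @param feature Numeric vector.
#' @param labels Class labels, same length.
#' @return Sorted numeric vector of cut points (possibly empty).
#' @export
discretize_mdl <- function(feature, labels) {
  stopifnot(length(feature) == length(labels))
  y <- as.integer(factor(labels))
  ord <- order(feature)
  mdl_split(feature[ord], y[ord], nlevels = max(y))
}

mdl_split <- function(x, y, nlevels) {
  n <- length(x)
  if (n < 2) return(numeric(0))
  # candidate cuts: midpoints between adjacent distinct values
  distinct <- which(diff(x) > 0)
  if (!length(distinct)) return(numeric(0))
  counts <- matrix(0L, nrow = n, ncol = nlevels)
  counts[cbind(seq_len(n), y)] <- 1L
  cum <- apply(counts, 2, cumsum)
  total <- cum[n, ]
  ent_all <- entropy_counts(total)
  best <- NULL
  best_ent <- Inf
  for (i in distinct) {
    left <- cum[i, ]; right <- total - left
    e <- (i / n) * entropy_counts(left) + ((n - i) / n) * entropy_counts(right)
    if (e < best_ent - 1e-12) {
      best_ent <- e
      best <- i
    }
  }
  gain <- ent_all - best_ent
  left <- cum[best, ]; right <- total - left
  k <- sum(total > 0); k1 <- sum(left > 0); k2 <- sum(right > 0)
  delta <- log2(3^k - 2) -
    (k * ent_all - k1 * entropy_counts(left) - k2 * entropy_counts(right))
  if (gain <= (log2(n - 1) + delta) / n) return(numeric(0))
  cut <- (x[best] + x[best + 1]) / 2
  sort(c(
    mdl_split(x[seq_len(best)], y[seq_len(best)], nlevels),
    cut,
    mdl_split(x[(best + 1):n], y[(best + 1):n], nlevels)
  ))
}

discretize_width <- function(feature, bins = 10) {
  r <- range(feature)
  if (diff(r) <= 0) return(numeric(0))
  r[1] + diff(r) * seq_len(bins - 1) / bins
}

apply_cuts <- function(feature, cuts) {
  if (!length(cuts)) return(rep.int(1L, length(feature)))
  findInterval(feature, sort(cuts)) + 1L
}

#' Information gain of a gene with respect to the class
#'
#' IG = H(labels) - H(labels | discretized gene). The gene is discretized
#' first (continuous expression values carry no finite joint counts):
#' `"mdl"` uses [discretize_mdl()], `"width"` equal-width bins, `"none"`
#' treats the values as already discrete.
#'
#' @param feature Numeric vector of expression values.
#' @param labels Class labels.
#' @param discretize Discretization method.
#' @param bins Bin count for `"width"`.
#' @return Information gain in bits (>= 0).
#' @export
information_gain <- function(feature, labels,
                             discretize = c("mdl", "width", "none"), bins = 10) {
  discretize <- match.arg(discretize)
  stopifnot(length(feature) == length(labels))
  xb <- switch(discretize,
    mdl = apply_cuts(feature, discretize_mdl(feature, labels)),
    width = apply_cuts(feature, discretize_width(feature, bins)),
    none = feature
  )
  max(0, mutual_information(xb, labels))
}

#' Symmetrical uncertainty between two discrete vectors
#'
#' SU = 2 I(X;Y) / (H(X) + H(Y)), a correlation-like association on \[0, 1\]
#' used as both the feature-class and feature-feature term of the CFS merit.
#' Defined as 0 when both entropies are 0.
#'
#' @param x,y Discrete vectors of equal length.
#' @return Value in \[0, 1\].
#' @export
symmetrical_uncertainty <- function(x, y) {
  hx <- entropy(x); hy <- entropy(y)
  if (hx + hy <= 0) return(0)
  su <- 2 * mutual_information(x, y) / (hx + hy)
  min(max(su, 0), 1)
}
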