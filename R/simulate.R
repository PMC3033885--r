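# Synthetic data generators emulating the study designs the classifier
# targets: a 2-D four-class illustrative scenario, a microarray-like
# many-genes/few-samples design with planted marker genes, and a fully
# separable design with guaranteed margins. All are deterministic under a
# fixed seed and never encode ground truth in gene ids.

#' Two-dimensional four-class scenario
#'
#' Four Gaussian blobs on two attributes. A fraction `overlap_fraction` of
#' each class's samples is re-drawn inside a neighbouring class's current
#' bounding region, so [detect_problematic()] finds a nonempty problematic
#' set whenever the fraction is positive.
#'
#' @param n_per_class Samples per class (>= 3).
#' @param overlap_fraction Fraction in \[0, 1\] of samples drawn inside a
#'   neighbour's bounding box (default 0.2).
#' @param seed Integer seed.
#' @param sd Within-class standard deviation (default 0.06).
#' @return An `expr_dataset` with classes `C1..C4` and genes `x`, `y`.
#' @export
make_fig2_scenario <- function(n_per_class = 20, overlap_fraction = 0.2,
                               seed = 1L, sd = 0.06) {
  stopifnot(n_per_class >= 3, overlap_fraction >= 0, overlap_fraction <= 1)
  rs <- local_rng(seed)
  centers <- rbind(c(0.25, 0.25), c(0.75, 0.25), c(0.25, 0.75), c(0.75, 0.75))
  K <- 4
  pts <- matrix(NA_real_, nrow = K * n_per_class, ncol = 2)
  labels <- rep(paste0("C", seq_len(K)), each = n_per_class)
  for (k in seq_len(K)) {
    rows <- (k - 1) * n_per_class + seq_len(n_per_class)
    pts[rows, ] <- cbind(rs$rnorm(n_per_class, centers[k, 1], sd),
                         rs$rnorm(n_per_class, centers[k, 2], sd))
  }
  n_overlap <- round(overlap_fraction * n_per_class)
  if (n_overlap > 0) {
    neighbour <- c(2, 1, 4, 3)  # horizontal neighbour shares a bounding band
    for (k in seq_len(K)) {
      nb_rows <- (neighbour[k] - 1) * n_per_class + seq_len(n_per_class)
      lo <- apply(pts[nb_rows, , drop = FALSE], 2, min)
      hi <- apply(pts[nb_rows, , drop = FALSE], 2, max)
      rows <- (k - 1) * n_per_class + seq_len(n_overlap)
      pts[rows, 1] <- lo[1] + rs$runif(n_overlap) * (hi[1] - lo[1])
      pts[rows, 2] <- lo[2] + rs$runif(n_overlap) * (hi[2] - lo[2])
    }
  }
  expression_dataset(pts, labels, gene_ids = c("x", "y"))
}

#' Microarray-like dataset with planted informative genes
#'
#' Noise genes draw log-normal positive intensities identically across
#' classes; planted genes add class-specific shifts on the log scale, spaced
#' `effect_size` within-class standard deviations apart. Ground truth (the
#' planted gene indices) is returned alongside the data, never encoded in the
#' gene ids.
#'
#' @param n_genes Total genes (default 500).
#' @param n_planted Planted informative genes (default 5).
#' @param n_per_class Samples per class (default 20).
#' @param n_classes Classes (default 3).
#' @param effect_size Class separation of planted genes in units of the
#'   within-class log-scale sd (default 3).
#' @param sdlog Within-class log-scale sd (default 0.25).
#' @param meanlog Baseline log intensity (default 6, i.e. intensities around
#'   exp(6) ~ 400).
#' @param noise `"lognormal"` (default) or `"gaussian"`.
#' @param seed Integer seed.
#' @return List with `data` (an `expr_dataset`) and `planted` (integer gene
#'   indices).
#' @export
make_microarray <- function(n_genes = 500, n_planted = 5, n_per_class = 20,
                            n_classes = 3, effect_size = 3, sdlog = 0.25,
                            meanlog = 6, noise = c("lognormal", "gaussian"),
                            seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(n_planted <= n_genes, n_per_class >= 2, n_classes >= 2,
            effect_size >= 0, sdlog > 0)
  rs <- local_rng(seed)
  n <- n_per_class * n_classes
  labels <- rep(paste0("C", seq_len(n_classes)), each = n_per_class)
  # gene-specific baselines so noise genes differ from each other but not
  # across classes
  base <- rs$rnorm(n_genes, meanlog, 0.5)
  logval <- matrix(rs$rnorm(n * n_genes, 0, sdlog), nrow = n) +
    matrix(base, nrow = n, ncol = n_genes, byrow = TRUE)
  planted <- sort(rs$sample_int(n_genes, n_planted))
  cls <- rep(seq_len(n_classes), each = n_per_class)
  for (j in seq_along(planted)) {
    # rotate which class sits where so no single class drives every marker
    shift_order <- ((seq_len(n_classes) + j - 2) %% n_classes)
    logval[, planted[j]] <- logval[, planted[j]] +
      effect_size * sdlog * shift_order[cls]
  }
  values <- if (noise == "lognormal") exp(logval) else logval
  list(data = expression_dataset(values, labels), planted = planted)
}

#' Fully separable dataset with guaranteed class margins
#'
#' Every gene gives each class a dedicated expression interval separated from
#' every other class by at least `margin` (the class order rotates across
#' genes so no single gene or direction dominates). Per-class bounding boxes
#' are therefore pairwise disjoint with at least `margin` separation on every
#' gene, which the generator asserts before returning.
#'
#' @param n_classes,n_per_class,n_genes Design size.
#' @param margin Minimum separation per gene (> 0, default 0.2).
#' @param seed Integer seed.
#' @return An `expr_dataset`.
#' @export
make_separable <- function(n_classes = 3, n_per_class = 10, n_genes = 5,
                           margin = 0.2, seed = 1L) {
  stopifnot(margin > 0, n_classes >= 2, n_per_class >= 1, n_genes >= 1)
  rs <- local_rng(seed)
  width <- 1
  n <- n_classes * n_per_class
  labels <- rep(paste0("C", seq_len(n_classes)), each = n_per_class)
  values <- matrix(NA_real_, nrow = n, ncol = n_genes)
  for (j in seq_len(n_genes)) {
    for (k in seq_len(n_classes)) {
      rows <- (k - 1) * n_per_class + seq_len(n_per_class)
      slot <- (k + j - 2) %% n_classes  # rotate class order across genes
      start <- slot * (width + 2 * margin)
      values[rows, j] <- start + rs$runif(n_per_class) * width
    }
  }
  out <- expression_dataset(values, labels)
  bounds <- class_bounds(out)
  for (i in seq_len(n_classes - 1)) {
    for (j in (i + 1):n_classes) {
      stopifnot(!boxes_overlap(bounds[[i]], bounds[[j]]))
    }
  }
  out
}
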