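# Shared fixture builders; everything is generated in code at test time.

tiny_dataset <- function(values, labels, ...) {
  expression_dataset(as.matrix(values), labels, ...)
}

# random small instance for the seed / LP / geometry oracle suites
random_instance <- function(seed, n_classes = NULL, per_class_max = 6,
                            genes = NULL) {
  rs_seed <- seed
  set.seed(rs_seed)
  K <- if (is.null(n_classes)) sample(2:4, 1) else n_classes
  m <- if (is.null(genes)) sample(2:5, 1) else genes
  sizes <- sample(seq_len(per_class_max - 1) + 1, K, replace = TRUE)
  values <- do.call(rbind, lapply(seq_len(K), function(k) {
    center <- runif(m)
    matrix(rnorm(sizes[k] * m, rep(center, each = sizes[k]), 0.25),
           nrow = sizes[k])
  }))
  labels <- rep(paste0("K", seq_len(K)), times = sizes)
  expression_dataset(values, labels)
}

# independent brute-force mutual information from a joint count table
mi_bruteforce <- function(joint) {
  n <- sum(joint)
  mi <- 0
  px <- rowSums(joint) / n
  py <- colSums(joint) / n
  for (i in seq_len(nrow(joint))) {
    for (j in seq_len(ncol(joint))) {
      p <- joint[i, j] / n
      if (p > 0) mi <- mi + p * log2(p / (px[i] * py[j]))
    }
  }
  mi
}

# independent quadrature of the F density
f_cdf_quadrature <- function(x, v1, v2) {
  dens <- function(t) {
    exp((v1 / 2) * log(v1 / v2) + (v1 / 2 - 1) * log(t) -
          ((v1 + v2) / 2) * log1p(v1 * t / v2) - lbeta(v1 / 2, v2 / 2))
  }
  if (x <= 0) return(0)
  stats::integrate(dens, 0, x, rel.tol = 1e-12, abs.tol = 1e-13)$value
}

# model-level geometry checks used by several suites
cross_class_overlaps <- function(boxes) {
  bad <- 0L
  nb <- length(boxes)
  if (nb < 2) return(0L)
  for (i in seq_len(nb - 1)) {
    for (j in (i + 1):nb) {
      if (boxes[[i]]$class_label != boxes[[j]]$class_label &&
          boxes_overlap(boxes[[i]], boxes[[j]])) {
        bad <- bad + 1L
      }
    }
  }
  bad
}

check_model_geometry <- function(model, data) {
  scaled <- suppressWarnings(apply_scaler(data, model$scaler))
  n_overlap <- cross_class_overlaps(model$boxes)
  bounds_ok <- all(vapply(model$boxes, function(b) {
    pts <- scaled$values[b$members, , drop = FALSE]
    isTRUE(all.equal(apply(pts, 2, min), b$lower)) &&
      isTRUE(all.equal(apply(pts, 2, max), b$upper))
  }, logical(1)))
  covered <- vapply(which(!model$training_flags), function(i) {
    any(vapply(model$boxes, function(b) {
      b$class_label == data$labels[i] &&
        all(scaled$values[i, ] >= b$lower - 1e-9) &&
        all(scaled$values[i, ] <= b$upper + 1e-9)
    }, logical(1)))
  }, logical(1))
  list(n_overlap = n_overlap, bounds_ok = bounds_ok, all_covered = all(covered))
}
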