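#' Fit per-gene min-max scaler parameters
#'
#' Records the per-gene minimum and maximum expression of a training set, the
#' statistics of the linear scaling x' = (x - min) / (max - min) applied to
#' every dataset before box construction.
#'
#' @param train An `expr_dataset` (training data only; using test data here
#'   would leak information into the scaler).
#' @return An object of class `hbe_scaler` with fields `min`, `max`
#'   (numeric, one per gene) and `gene_ids`.
#' @export
fit_scaler <- function(train) {
  stopifnot(inherits(train, "expr_dataset"), n_samples(train) >= 1)
  structure(
    list(min = apply(train$values, 2, min),
         max = apply(train$values, 2, max),
         gene_ids = train$gene_ids),
    class = "hbe_scaler"
  )
}

#' Apply min-max scaling
#'
#' Maps each entry to (x - min) / (max - min) using training-set extrema.
#' Training data lands in \[0, 1\]; test data may fall outside and is not
#' clamped. Genes that were constant in the training set (max == min) map to 0
#' with a warning: the division is undefined and the gene carries no
#' information.
#'
#' @param data An `expr_dataset` or a plain numeric matrix (samples x genes).
#' @param scaler An `hbe_scaler` from [fit_scaler()].
#' @return Scaled object of the same type as `data`.
#' @export
apply_scaler <- function(data, scaler) {
  stopifnot(inherits(scaler, "hbe_scaler"))
  values <- if (inherits(data, "expr_dataset")) data$values else as.matrix(data)
  if (ncol(values) != length(scaler$min)) {
    stop("gene count mismatch: data has ", ncol(values),
         " genes, scaler has ", length(scaler$min))
  }
  rng <- scaler$max - scaler$min
  flat <- rng <= 0
  if (any(flat)) {
    warning(sum(flat), " constant gene(s) in training data mapped to 0")
    rng[flat] <- 1
  }
  scaled <- sweep(sweep(values, 2, scaler$min, "-"), 2, rng, "/")
  if (any(flat)) scaled[, flat] <- 0
  if (inherits(data, "expr_dataset")) {
    out <- data
    out$values <- scaled
    out
  } else {
    scaled
  }
}
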