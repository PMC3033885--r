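#' Construct an expression dataset
#'
#' Container for a samples x genes expression matrix with one class label per
#' sample. Labels are kept as opaque strings; the ordered set of distinct
#' classes (`class_set`) uses first-appearance order so that all downstream
#' tie-breaking is stable.
#'
#' @param values Numeric matrix, samples in rows, genes in columns. No missing
#'   or non-finite entries are allowed.
#' @param labels Character vector of class labels, one per sample (row).
#' @param sample_ids Optional character vector of sample identifiers
#'   (default `s1..sn`).
#' @param gene_ids Optional character vector of gene identifiers
#'   (default `g1..gm`).
#' @param require_two_classes Validation switch; prediction inputs may carry a
#'   single placeholder class.
#'
#' @return An object of class `expr_dataset`: a list with elements `values`,
#'   `sample_ids`, `gene_ids`, `labels`, `class_set`.
#' @export
expression_dataset <- function(values, labels, sample_ids = NULL,
                               gene_ids = NULL, require_two_classes = TRUE) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  m <- ncol(values)
  labels <- as.character(labels)
  if (length(labels) != n) {
    stop("number of labels (", length(labels),
         ") does not match number of samples (", n, ")")
  }
  if (anyNA(values) || !all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, , drop = TRUE]
    stop("non-finite expression value at sample ", bad[1], ", gene ", bad[2])
  }
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  if (is.null(gene_ids)) {
    gene_ids <- colnames(values)
    if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(m))
  }
  if (length(sample_ids) != n) stop("sample_ids length mismatch")
  if (length(gene_ids) != m) stop("gene_ids length mismatch")
  class_set <- unique(labels)
  if (require_two_classes && length(class_set) < 2) {
    stop("dataset must contain at least 2 classes, found ",
         length(class_set))
  }
  dimnames(values) <- NULL
  structure(
    list(values = values, sample_ids = as.character(sample_ids),
         gene_ids = as.character(gene_ids), labels = labels,
         class_set = class_set),
    class = "expr_dataset"
  )
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat("<expr_dataset> ", nrow(x$values), " samples x ", ncol(x$values),
      " genes, classes: ", paste(x$class_set, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.expr_dataset <- function(x) dim(x$values)

#' Number of samples / genes in a dataset
#' @param data An `expr_dataset`.
#' @return Integer count.
#' @export
n_samples <- function(data) nrow(data$values)

#' @rdname n_samples
#' @export
n_genes <- function(data) ncol(data$values)

#' Restrict a dataset to a subset of samples and/or genes
#'
#' @param data An `expr_dataset`.
#' @param samples Integer indices of samples to keep (default all).
#' @param genes Integer indices of genes to keep (default all).
#' @param require_two_classes Passed through to [expression_dataset()].
#' @return The restricted `expr_dataset`. The class set is recomputed in
#'   first-appearance order of the retained samples.
#' @export
subset_dataset <- function(data, samples = NULL, genes = NULL,
                           require_two_classes = TRUE) {
  if (is.null(samples)) samples <- seq_len(n_samples(data))
  if (is.null(genes)) genes <- seq_len(n_genes(data))
  expression_dataset(
    data$values[samples, genes, drop = FALSE],
    labels = data$labels[samples],
    sample_ids = data$sample_ids[samples],
    gene_ids = data$gene_ids[genes],
    require_two_classes = require_two_classes
  )
}

# integer class index (position in class_set) per sample
class_index <- function(data) match(data$labels, data$class_set)
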