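# Evaluation protocols. Gene selection (when requested) and scaling are
# always refit inside each training fold, so no information from held-out
# samples reaches the model; selection outside the folds is available as an
# explicitly labeled legacy mode.

cv_result <- function(protocol, per_fold, predictions, repeats, seed,
                      sd_defined = TRUE, sd_value = NULL, selection_mode = "none") {
  mean_acc <- mean(per_fold)
  structure(list(protocol = protocol,
                 per_fold_accuracy = per_fold,
                 mean_accuracy = mean_acc,
                 sd_accuracy = if (!sd_defined) 0 else sd_value,
                 sd_defined = sd_defined,
                 predictions = predictions,
                 repeats = repeats, seed = seed,
                 selection_mode = selection_mode),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", x$protocol, ": ",
      formatC(x$mean_accuracy, digits = 4, format = "f"), "%",
      if (x$sd_defined) paste0(" ± ", formatC(x$sd_accuracy, digits = 3,
                                                   format = "f")) else "",
      " (", x$repeats, " repeat(s), seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

# default classifier hooks; swappable for harness sanity checks
hbe_hooks <- function(control) {
  list(
    fit = function(train) hbe_fit(train, control),
    predict = function(model, test) predict(model, test$values, raw = TRUE)
  )
}

#' Majority-class dummy classifier hooks
#'
#' Predicts the most frequent training class for every sample (ties to the
#' class seen first). A sanity baseline for the evaluation harness: its
#' accuracy equals the majority-class fraction.
#'
#' @return List with `fit` and `predict` functions usable as
#'   `hooks` in [cross_validate()].
#' @export
majority_hooks <- function() {
  list(
    fit = function(train) {
      counts <- table(factor(train$labels, levels = train$class_set))
      names(counts)[which.max(counts)]
    },
    predict = function(model, test) rep(model, n_samples(test))
  )
}

select_genes_for_fold <- function(train, select) {
  if (is.null(select)) return(seq_len(n_genes(train)))
  if (!is.null(select$genes)) return(as.integer(select$genes))
  args <- select
  args$genes <- NULL
  rank_genes(train, method = args$method, top_n = args$top_n)$genes
}

#' Evaluate on a held-out test set
#'
#' Fits on the training data (scaler and any gene selection from the training
#' data only) and reports percent accuracy on the test set.
#'
#' @param train,test `expr_dataset`s on the same gene set.
#' @param control [hbe_control()].
#' @param select `NULL` (use all genes), a list
#'   `list(method=, top_n=)` for per-fit filter selection, or
#'   `list(genes=)` for a fixed gene set.
#' @param hooks Classifier hooks (default HBE).
#' @return A `cv_result` with protocol `"test_set"`.
#' @export
evaluate_test <- function(train, test, control = hbe_control(),
                          select = NULL, hooks = NULL) {
  if (!all(test$labels %in% train$class_set)) {
    stop("test labels outside training classes: ",
         paste(setdiff(test$labels, train$class_set), collapse = ", "))
  }
  if (is.null(hooks)) hooks <- hbe_hooks(control)
  genes <- select_genes_for_fold(train, select)
  tr <- subset_dataset(train, genes = genes)
  te <- subset_dataset(test, genes = genes, require_two_classes = FALSE)
  model <- hooks$fit(tr)
  pred <- hooks$predict(model, te)
  acc <- 100 * mean(pred == te$labels)
  cv_result("test_set", acc,
            data.frame(sample_id = te$sample_ids, true = te$labels,
                       predicted = pred),
            repeats = 1L, seed = NA_integer_, sd_defined = FALSE,
            selection_mode = if (is.null(select)) "none" else "train_only")
}

#' Repeated stratified k-fold cross-validation
#'
#' Each repeat draws a fresh stratified fold plan (seed offset by the repeat
#' index); scaling and gene selection are refit inside every training fold
#' unless `selection = "outside"` is requested explicitly. The reported mean
#' is the mean over repeats of the per-repeat mean fold accuracy; the
#' standard deviation is over repeat means by default, or over individual
#' folds with `sd_over = "folds"`.
#'
#' @param data An `expr_dataset`.
#' @param k Fold count (>= 2; `k = n` gives LOOCV folds).
#' @param repeats Number of repeats (default 1).
#' @param seed Base seed for the fold plans.
#' @param control [hbe_control()].
#' @param select As in [evaluate_test()].
#' @param selection `"inside"` (default, refit per fold) or `"outside"`
#'   (select once on all data; legacy protocol, labeled in the result).
#' @param sd_over `"repeats"` (default) or `"folds"`.
#' @param stratified Stratify folds (default TRUE; forced off when `k = n`).
#' @param hooks Classifier hooks (default HBE).
#' @return A `cv_result`.
#' @export
cross_validate <- function(data, k = 10, repeats = 1, seed = 1L,
                           control = hbe_control(), select = NULL,
                           selection = c("inside", "outside"),
                           sd_over = c("repeats", "folds"),
                           stratified = TRUE, hooks = NULL) {
  selection <- match.arg(selection)
  sd_over <- match.arg(sd_over)
  if (k < 2) stop("k must be >= 2")
  if (is.null(hooks)) hooks <- hbe_hooks(control)
  if (selection == "outside" && !is.null(select)) {
    genes <- select_genes_for_fold(data, select)
    select <- list(genes = genes)
  }
  all_fold_acc <- c()
  repeat_means <- numeric(repeats)
  preds <- list()
  for (r in seq_len(repeats)) {
    plan <- make_folds(data, k, seed = seed + r - 1L, stratified = stratified)
    fold_acc <- numeric(k)
    for (f in seq_len(k)) {
      te_idx <- which(plan$assignments == f)
      tr_idx <- setdiff(seq_len(n_samples(data)), te_idx)
      train <- subset_dataset(data, samples = tr_idx)
      test <- subset_dataset(data, samples = te_idx, require_two_classes = FALSE)
      genes <- select_genes_for_fold(train, select)
      model <- hooks$fit(subset_dataset(train, genes = genes))
      pred <- hooks$predict(model, subset_dataset(test, genes = genes,
                                                  require_two_classes = FALSE))
      fold_acc[f] <- 100 * mean(pred == test$labels)
      preds[[length(preds) + 1]] <-
        data.frame(repeat_ = r, fold = f, sample_id = test$sample_ids,
                   true = test$labels, predicted = pred)
    }
    all_fold_acc <- c(all_fold_acc, fold_acc)
    repeat_means[r] <- mean(fold_acc)
  }
  sd_defined <- (sd_over == "repeats" && repeats > 1) ||
    (sd_over == "folds" && length(all_fold_acc) > 1)
  sd_value <- if (!sd_defined) NULL
    else if (sd_over == "repeats") stats::sd(repeat_means)
    else stats::sd(all_fold_acc)
  out <- cv_result("kfold", all_fold_acc, do.call(rbind, preds),
                   repeats = repeats, seed = as.integer(seed),
                   sd_defined = sd_defined, sd_value = sd_value,
                   selection_mode = if (is.null(select)) "none" else selection)
  out$mean_accuracy <- mean(repeat_means)
  out$repeat_means <- repeat_means
  out
}

#' Leave-one-out cross-validation
#'
#' n single-holdout fits; accuracy is the percentage of held-out samples
#' predicted correctly. A fold-to-fold standard deviation is not meaningful
#' for single-sample folds and is reported as 0 with `sd_defined = FALSE`.
#'
#' @inheritParams cross_validate
#' @return A `cv_result` with protocol `"loocv"`.
#' @export
loocv <- function(data, control = hbe_control(), select = NULL,
                  selection = c("inside", "outside"), hooks = NULL) {
  n <- n_samples(data)
  if (n < 2) stop("need at least 2 samples")
  out <- cross_validate(data, k = n, repeats = 1, seed = 0L, control = control,
                        select = select, selection = selection,
                        stratified = FALSE, hooks = hooks)
  out$protocol <- "loocv"
  out$sd_defined <- FALSE
  out$sd_accuracy <- 0
  out
}
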