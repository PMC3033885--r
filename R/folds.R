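#' Build a reproducible cross-validation fold plan
#'
#' Randomly assigns samples to k folds of near-equal size (differing by at
#' most one sample). Stratified plans (the default for class-imbalanced
#' expression data) preserve class proportions within one sample per fold.
#' `k == n` gives leave-one-out folds. Deterministic given `seed`.
#'
#' @param data An `expr_dataset`.
#' @param k Number of folds, `2 <= k <= n`.
#' @param seed Integer seed.
#' @param stratified Stratify on class labels (requires `k` at most the
#'   smallest class size).
#' @return An object of class `fold_plan`: list with `k`, `seed`,
#'   `assignments` (fold index per sample).
#' @export
make_folds <- function(data, k, seed = 1L, stratified = TRUE) {
  n <- n_samples(data)
  k <- as.integer(k)
  if (k < 1 || k > n) stop("k must be between 1 and the number of samples (", n, ")")
  if (stratified) {
    sizes <- table(data$labels)
    if (k > min(sizes)) {
      if (k == n) {
        stratified <- FALSE  # LOOCV: stratification is meaningless
      } else {
        stop("stratified folds need k <= smallest class size (", min(sizes), ")")
      }
    }
  }
  assignments <- integer(n)
  rs <- local_rng(seed)
  if (stratified) {
    # deal each class's shuffled samples to folds in order of current load, so
    # per-class counts stay within +/-1 of proportionality and global fold
    # sizes stay within 1 of each other
    loads <- integer(k)
    for (cl in data$class_set) {
      idx <- which(data$labels == cl)
      idx <- idx[rs$sample_int(length(idx))]
      ord <- order(loads, seq_len(k))
      dealt <- rep_len(ord, length(idx))
      assignments[idx] <- dealt
      loads <- loads + tabulate(dealt, nbins = k)
    }
  } else {
    idx <- rs$sample_int(n)
    assignments[idx] <- rep_len(seq_len(k), n)
  }
  structure(list(k = k, seed = as.integer(seed), assignments = assignments),
            class = "fold_plan")
}

#' Serialize / read a fold plan as JSON
#' @param plan A `fold_plan`.
#' @param path File path.
#' @return `read_fold_plan` returns a `fold_plan`.
#' @export
write_fold_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fold_plan
#' @export
read_fold_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(k = as.integer(x$k), seed = as.integer(x$seed),
                 assignments = as.integer(x$assignments)),
            class = "fold_plan")
}

# Self-contained RNG stream so package randomness never disturbs (or is
# disturbed by) the caller's .Random.seed.
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, globalenv())
  }
  with_state <- function(f) {
    function(...) {
      outer <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", env$state, globalenv())
      on.exit({
        env$state <- get(".Random.seed", globalenv())
        if (is.null(outer)) rm(".Random.seed", envir = globalenv())
        else assign(".Random.seed", outer, globalenv())
      })
      f(...)
    }
  }
  list(
    sample_int = with_state(function(n, size = n) sample.int(n, size)),
    runif = with_state(stats::runif),
    rnorm = with_state(stats::rnorm),
    rlnorm = with_state(stats::rlnorm)
  )
}
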