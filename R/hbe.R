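#' Control parameters for hyper-box fitting
#'
#' @param max_boxes_per_class MILP box budget per class (default 2).
#' @param lambda_box Objective weight on the box count (default 1).
#' @param max_rounds Refinement rounds for [detect_problematic()] (default 2).
#' @param seeds_on `"all"` computes seeds on all training samples (default);
#'   `"problematic"` restricts the seed model to the problematic samples.
#' @return A list of class `hbe_control`.
#' @export
hbe_control <- function(max_boxes_per_class = 2, lambda_box = 1,
                        max_rounds = 2, seeds_on = c("all", "problematic")) {
  structure(list(max_boxes_per_class = max_boxes_per_class,
                 lambda_box = lambda_box, max_rounds = max_rounds,
                 seeds_on = match.arg(seeds_on)),
            class = "hbe_control")
}

#' Fit a hyper-box enclosure classifier
#'
#' Pipeline: min-max scale the training data; detect problematic samples
#' (those inside a foreign class's bounding box); find one seed per class by
#' the seed IP; build optimal boxes for the problematic samples with the MILP
#' model; enclose the remaining samples in one defined box per class; then
#' eliminate every cross-class box intersection. When no sample is
#' problematic the MILP stage is skipped and each class gets its bounding
#' box directly.
#'
#' @param data An `expr_dataset` (unscaled; already restricted to the genes
#'   the model should use).
#' @param control An [hbe_control()] list.
#' @return An object of class `hbe_model`: `scaler`, `selected_genes` (gene
#'   ids), `boxes`, `class_set`, `training_flags` (samples the MILP left
#'   misclassified), `partition`, `seeds`.
#' @export
hbe_fit <- function(data, control = hbe_control()) {
  if (length(data$class_set) < 2) stop("need at least 2 classes to fit")
  scaler <- fit_scaler(data)
  scaled <- suppressWarnings(apply_scaler(data, scaler))
  partition <- detect_problematic(scaled, max_rounds = control$max_rounds)
  flags <- logical(n_samples(data))
  if (length(partition$problematic)) {
    seeds <- if (control$seeds_on == "all") {
      find_seeds(scaled)
    } else {
      sub <- subset_dataset(scaled, samples = partition$problematic,
                            require_two_classes = FALSE)
      s <- find_seeds(sub)
      s$seed_index <- partition$problematic[s$seed_index]
      s
    }
    milp <- build_boxes_milp(scaled, partition$problematic, seeds,
                             max_boxes_per_class = control$max_boxes_per_class,
                             lambda_box = control$lambda_box)
    flags[as.integer(names(milp$misclassified))] <- milp$misclassified
    rest <- setdiff(partition$non_problematic, unname(seeds$seed_index))
    boxes <- c(milp$boxes, enclose_nonproblematic(scaled, rest))
  } else {
    seeds <- NULL
    boxes <- enclose_nonproblematic(scaled, seq_len(n_samples(data)))
  }
  boxes <- eliminate_intersections(boxes, scaled$values, scaled$class_set)
  structure(
    list(scaler = scaler, selected_genes = data$gene_ids, boxes = boxes,
         class_set = data$class_set, training_flags = flags,
         partition = partition, seeds = seeds),
    class = "hbe_model"
  )
}

#' @export
print.hbe_model <- function(x, ...) {
  cat("<hbe_model> ", length(x$boxes), " boxes over ",
      length(x$selected_genes), " genes, classes: ",
      paste(x$class_set, collapse = ", "), "\n", sep = "")
  if (any(x$training_flags)) {
    cat("training samples flagged misclassified:",
        sum(x$training_flags), "\n")
  }
  invisible(x)
}

#' Predict classes with a fitted hyper-box model
#'
#' A query point inside a box takes that box's class (cross-class containment
#' is impossible after intersection elimination). A point outside every box
#' takes the class of the nearest box by Euclidean point-to-box distance;
#' ties break to the smaller box volume, then to the class earlier in the
#' model's class set, then to box order.
#'
#' @param object An `hbe_model`.
#' @param newdata Numeric matrix/vector (samples x genes on the model's gene
#'   set) or an `expr_dataset`.
#' @param raw If `TRUE` (default) `newdata` is on the original expression
#'   scale and the model's scaler is applied first; set `FALSE` for already
#'   scaled values.
#' @param ... Unused.
#' @return Character vector of predicted class labels.
#' @export
predict.hbe_model <- function(object, newdata, raw = TRUE, ...) {
  values <- if (inherits(newdata, "expr_dataset")) newdata$values else newdata
  if (is.null(dim(values))) values <- matrix(values, nrow = 1)
  if (ncol(values) != length(object$scaler$min)) {
    stop("query has ", ncol(values), " genes, model expects ",
         length(object$scaler$min))
  }
  if (raw) values <- suppressWarnings(apply_scaler(values, object$scaler))
  boxes <- object$boxes
  # volumes are compared at 12 significant digits so the smaller-volume tie
  # rule is immune to floating-point dust in the bound arithmetic
  vol <- signif(vapply(boxes, function(b) prod(b$upper - b$lower), numeric(1)), 12)
  cls_rank <- vapply(boxes, function(b) match(b$class_label, object$class_set),
                     numeric(1))
  vapply(seq_len(nrow(values)), function(i) {
    p <- values[i, ]
    d <- vapply(boxes, function(b) point_box_distance(p, b), numeric(1))
    inside <- d <= 0
    cand <- if (any(inside)) which(inside) else which(d <= min(d) + 1e-12)
    pick <- cand[order(vol[cand], cls_rank[cand], cand)][1]
    as.character(boxes[[pick]]$class_label)
  }, character(1))
}

#' Serialize a fitted model to JSON
#'
#' Writes the selected genes, scaler parameters and every box (class, lower,
#' upper, origin, members) as a JSON document; [read_hbe_model()] restores
#' the model.
#'
#' @param model An `hbe_model`.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_hbe_model <- function(model, path) {
  doc <- list(
    selected_genes = model$selected_genes,
    class_set = model$class_set,
    scaler = list(min = model$scaler$min, max = model$scaler$max,
                  gene_ids = model$scaler$gene_ids),
    training_flags = model$training_flags,
    boxes = lapply(model$boxes, function(b) {
      list(class = as.character(b$class_label), lower = b$lower,
           upper = b$upper, origin = b$origin, members = b$members)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hbe_model
#' @export
read_hbe_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  boxes <- lapply(seq_len(nrow(doc$boxes)), function(r) {
    hyper_box(doc$boxes$class[r], doc$boxes$lower[[r]], doc$boxes$upper[[r]],
              members = doc$boxes$members[[r]], origin = doc$boxes$origin[r])
  })
  structure(
    list(scaler = structure(list(min = doc$scaler$min, max = doc$scaler$max,
                                 gene_ids = doc$scaler$gene_ids),
                            class = "hbe_scaler"),
         selected_genes = doc$selected_genes, boxes = boxes,
         class_set = doc$class_set, training_flags = doc$training_flags,
         partition = NULL, seeds = NULL),
    class = "hbe_model"
  )
}
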