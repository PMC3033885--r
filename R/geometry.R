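#' Construct a hyper-box
#'
#' The geometric unit of the classifier: an axis-aligned region
#' \[lower, upper\] in scaled expression space carrying one class label and
#' the indices of the training samples it encloses. A box built from its
#' members always has bounds equal to their componentwise extrema; a
#' single-member box is a point box.
#'
#' @param class_label Class identifier.
#' @param lower,upper Numeric bound vectors (one entry per gene),
#'   `lower <= upper` componentwise.
#' @param members Integer indices of enclosed training samples.
#' @param origin `"milp"` (built by the optimization model), `"defined"`
#'   (extrema of non-problematic samples) or `"split"` (regrouped during
#'   intersection elimination).
#' @return An object of class `hyper_box`.
#' @export
hyper_box <- function(class_label, lower, upper, members = integer(0),
                      origin = c("milp", "defined", "split")) {
  origin <- match.arg(origin)
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != length(upper)) stop("bound length mismatch")
  if (any(lower > upper + 1e-12)) stop("lower bound exceeds upper bound")
  structure(list(class_label = class_label, lower = lower, upper = upper,
                 members = as.integer(members), origin = origin),
            class = "hyper_box")
}

#' @export
print.hyper_box <- function(x, ...) {
  cat("<hyper_box> class=", x$class_label, " origin=", x$origin,
      " members=", length(x$members), " dims=", length(x$lower), "\n", sep = "")
  invisible(x)
}

box_from_members <- function(values, members, class_label, origin) {
  pts <- values[members, , drop = FALSE]
  hyper_box(class_label, apply(pts, 2, min), apply(pts, 2, max),
            members = members, origin = origin)
}

#' Per-class bounding boxes
#'
#' Componentwise min and max of each class's samples: the tightest
#' axis-aligned box containing the class.
#'
#' @param data An `expr_dataset` (typically scaled).
#' @return Named list (one entry per class in `class_set` order) of
#'   `hyper_box` objects with origin `"defined"`.
#' @export
class_bounds <- function(data) {
  out <- lapply(data$class_set, function(cl) {
    idx <- which(data$labels == cl)
    box_from_members(data$values, idx, cl, "defined")
  })
  names(out) <- data$class_set
  out
}

point_in_box <- function(point, box, tol = 1e-12) {
  all(point >= box$lower - tol & point <= box$upper + tol)
}

points_in_box <- function(values, box, tol = 1e-12) {
  inside <- rep(TRUE, nrow(values))
  for (m in seq_along(box$lower)) {
    inside <- inside & values[, m] >= box$lower[m] - tol &
      values[, m] <= box$upper[m] + tol
  }
  inside
}

#' Do two hyper-boxes overlap?
#'
#' Closed-interval convention: boxes overlap iff their intervals intersect on
#' every gene, so boundary contact counts as overlap. This keeps containment
#' during prediction unambiguous after cross-class overlaps are eliminated.
#'
#' @param a,b `hyper_box` objects of equal dimensionality.
#' @return Logical.
#' @export
boxes_overlap <- function(a, b) {
  if (length(a$lower) != length(b$lower)) {
    stop("boxes have different dimensionality (", length(a$lower), " vs ",
         length(b$lower), ")")
  }
  all(pmax(a$lower, b$lower) <= pmin(a$upper, b$upper))
}

overlap_volume <- function(a, b) {
  prod(pmax(0, pmin(a$upper, b$upper) - pmax(a$lower, b$lower)))
}

#' Euclidean distance between two sample vectors
#'
#' @param a,b Numeric vectors of equal length.
#' @return Non-negative Euclidean norm of `a - b`.
#' @export
pairwise_distance <- function(a, b) {
  if (length(a) != length(b)) stop("vectors have different lengths")
  sqrt(sum((a - b)^2))
}

# Euclidean distance from a point to a box (componentwise distance to the
# interval, then the norm); 0 inside the box.
point_box_distance <- function(point, box) {
  d <- pmax(box$lower - point, 0, point - box$upper)
  sqrt(sum(d^2))
}

#' Detect problematic samples
#'
#' A training sample is "problematic" when it lies inside the bounding box of
#' at least one foreign class, so single per-class boxes cannot separate it.
#' Each refinement round refits the class bounds on the currently
#' non-problematic samples only and re-marks all samples against the refitted
#' (never larger) boxes, which monotonically reduces the problematic set;
#' iteration stops at `max_rounds` refinements or at a fixpoint.
#'
#' @param data A scaled `expr_dataset` with >= 2 classes.
#' @param max_rounds Number of refinement rounds after the initial marking
#'   (default 2).
#' @return An object of class `problem_partition`: list with integer vectors
#'   `problematic` and `non_problematic`, the `class_bounds` used for the
#'   final marking, and `rounds` actually run.
#' @export
detect_problematic <- function(data, max_rounds = 2L) {
  if (length(data$class_set) < 2) stop("need at least 2 classes")
  n <- n_samples(data)
  mark <- function(bounds) {
    prob <- rep(FALSE, n)
    for (cl in data$class_set) {
      box <- bounds[[cl]]
      if (is.null(box)) next
      foreign <- data$labels != cl
      prob[foreign] <- prob[foreign] |
        points_in_box(data$values[foreign, , drop = FALSE], box)
    }
    prob
  }
  bounds <- class_bounds(data)
  prob <- mark(bounds)
  rounds <- 0L
  while (rounds < max_rounds && any(prob)) {
    keep <- which(!prob)
    if (!all(data$class_set %in% data$labels[keep])) break  # a class vanished
    sub_bounds <- lapply(data$class_set, function(cl) {
      idx <- keep[data$labels[keep] == cl]
      box_from_members(data$values, idx, cl, "defined")
    })
    names(sub_bounds) <- data$class_set
    new_prob <- mark(sub_bounds)
    rounds <- rounds + 1L
    if (identical(new_prob, prob)) break
    prob <- new_prob
    bounds <- sub_bounds
  }
  structure(list(problematic = which(prob), non_problematic = which(!prob),
                 class_bounds = bounds, rounds = rounds),
            class = "problem_partition")
}
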