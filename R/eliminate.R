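#' Enclose non-problematic samples in per-class boxes
#'
#' One "defined" box per class with members among the given samples, bounds
#' equal to the componentwise extrema of that class's samples. Classes with no
#' samples in the subset get no box.
#'
#' @param data A scaled `expr_dataset`.
#' @param samples Integer indices of the (non-problematic) samples to enclose.
#' @return List of `hyper_box` objects with origin `"defined"`.
#' @export
enclose_nonproblematic <- function(data, samples) {
  samples <- as.integer(samples)
  out <- list()
  for (cl in data$class_set) {
    idx <- samples[data$labels[samples] == cl]
    if (!length(idx)) next
    out[[length(out) + 1]] <- box_from_members(data$values, idx, cl, "defined")
  }
  out
}

#' Eliminate cross-class box intersections
#'
#' Iteratively removes samples from overlapping boxes until no two boxes with
#' different class labels overlap. At each step the offending pair is chosen
#' deterministically (pairs containing a defined/split box before pure milp
#' pairs, then lowest class index, then largest overlap volume, then box
#' order); the pair's defined/split box sheds its members lying inside the
#' other box (or, when none lie inside, the member nearest the overlap
#' region) into a new "split" box, and both bounds are recomputed. When the
#' preferred box cannot strictly shrink (it is a point box, or all of its
#' members would leave) the roles swap; when neither box can shrink the data
#' contain identical points with different labels and an inconsistent-data
#' error is raised. Every step strictly reduces some box's member count, so
#' the procedure terminates.
#'
#' @param boxes List of `hyper_box` objects, each with >= 1 member; member
#'   sets disjoint.
#' @param values Scaled training matrix the member indices refer to.
#' @param class_set Ordered class vector used for the lowest-class-index tie
#'   rule; defaults to first appearance among `boxes`.
#' @return List of `hyper_box` objects with no cross-class overlap; empty
#'   boxes are dropped, box bounds equal member extrema.
#' @export
eliminate_intersections <- function(boxes, values, class_set = NULL) {
  stopifnot(all(vapply(boxes, function(b) length(b$members) >= 1, logical(1))))
  if (is.null(class_set)) {
    class_set <- unique(vapply(boxes, function(b) as.character(b$class_label),
                               character(1)))
  }
  repeat {
    pairs <- offending_pairs(boxes, class_set)
    if (!nrow(pairs)) break
    pr <- pairs[1, ]
    a <- boxes[[pr$i]]; b <- boxes[[pr$j]]
    # preferred shrink target: the defined/split box of the pair
    first_pref <- if (a$origin != "milp") c(pr$i, pr$j) else if (b$origin != "milp") c(pr$j, pr$i) else c(pr$i, pr$j)
    res <- try_shrink(boxes[[first_pref[1]]], boxes[[first_pref[2]]], values)
    target <- first_pref[1]
    if (is.null(res)) {
      res <- try_shrink(boxes[[first_pref[2]]], boxes[[first_pref[1]]], values)
      target <- first_pref[2]
    }
    if (is.null(res)) {
      pa <- boxes[[pr$i]]; pb <- boxes[[pr$j]]
      stop("inconsistent data: samples {",
           paste(pa$members, collapse = ","), "} (class ", pa$class_label,
           ") and {", paste(pb$members, collapse = ","), "} (class ",
           pb$class_label, ") occupy identical coordinates")
    }
    keep <- setdiff(boxes[[target]]$members, res$removed)
    new_boxes <- boxes[-target]
    if (length(keep)) {
      new_boxes[[length(new_boxes) + 1]] <-
        box_from_members(values, keep, boxes[[target]]$class_label,
                         boxes[[target]]$origin)
    }
    new_boxes[[length(new_boxes) + 1]] <-
      box_from_members(values, res$removed, boxes[[target]]$class_label, "split")
    boxes <- new_boxes
  }
  boxes
}

# All cross-class overlapping pairs, ordered by the deterministic rule.
# Returns a data.frame with columns i, j (indices into boxes).
offending_pairs <- function(boxes, class_set) {
  nb <- length(boxes)
  out <- list()
  if (nb >= 2) {
    for (i in seq_len(nb - 1)) {
      for (j in (i + 1):nb) {
        if (boxes[[i]]$class_label == boxes[[j]]$class_label) next
        if (!boxes_overlap(boxes[[i]], boxes[[j]])) next
        out[[length(out) + 1]] <- c(i, j)
      }
    }
  }
  if (!length(out)) return(data.frame(i = integer(0), j = integer(0)))
  pm <- do.call(rbind, out)
  has_soft <- vapply(seq_len(nrow(pm)), function(r) {
    boxes[[pm[r, 1]]]$origin != "milp" || boxes[[pm[r, 2]]]$origin != "milp"
  }, logical(1))
  vol <- vapply(seq_len(nrow(pm)), function(r) {
    overlap_volume(boxes[[pm[r, 1]]], boxes[[pm[r, 2]]])
  }, numeric(1))
  cls_rank <- vapply(seq_len(nrow(pm)), function(r) {
    min(match(boxes[[pm[r, 1]]]$class_label, class_set),
        match(boxes[[pm[r, 2]]]$class_label, class_set))
  }, numeric(1))
  ord <- order(!has_soft, cls_rank, -vol, pm[, 1], pm[, 2])
  data.frame(i = pm[ord, 1], j = pm[ord, 2])
}

# Members of `box` to shed so the box strictly shrinks relative to `other`.
# NULL when the box cannot strictly shrink.
try_shrink <- function(box, other, values) {
  mem <- box$members
  if (length(mem) < 2) return(NULL)
  inside <- mem[points_in_box(values[mem, , drop = FALSE], other)]
  if (length(inside) == length(mem)) {
    # all members inside the other box: shed all but the lowest-index member
    return(list(removed = sort(inside)[-1]))
  }
  if (length(inside)) return(list(removed = inside))
  # no member inside: shed the single member nearest the overlap region
  olap <- hyper_box(box$class_label,
                    pmax(box$lower, other$lower), pmin(box$upper, other$upper))
  d <- vapply(mem, function(i) point_box_distance(values[i, ], olap), numeric(1))
  list(removed = mem[which.min(d)])
}
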