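# MILP construction of class-labeled hyper-boxes for problematic samples.
#
# Model (binary x[i,b] sample-in-box, z[b,k] box-class, u[b] box-used,
# y[i,k] misclassification; continuous bounds L[b,m] <= U[b,m] in [0,1]):
#   min  sum(y) + lambda_box * sum(u)
#   s.t. sum_b x[i,b] = 1                       (one box per sample)
#        sum_k z[b,k] = u[b]                    (one class per used box)
#        x[i,b] <= u[b]
#        L[b,m] <= a[i,m] + (1 - x[i,b]),  U[b,m] >= a[i,m] - (1 - x[i,b])
#        L[b,m] <= U[b,m] <= u[b]               (big-M = 1, data in [0,1])
#        y[i,k] >= x[i,b] + z[b,k] - 1  for k != class(i)
#        x[seed_k, b_k] = 1, z[b_k, k] = 1      (seed fixing)
# Box pool: one designated seed box per class plus (max_boxes_per_class - 1)
# free boxes per class. Cross-class box overlap is deliberately NOT forbidden
# here; it is resolved afterwards by eliminate_intersections().
#
# The model decomposes: bounds never bind (a used box can always take exactly
# the extrema of its assigned samples), and once the box-class variables z are
# fixed each sample independently takes a cheapest compatible box. The solver
# below therefore enumerates all box-class configurations of the free boxes
# (the only coupling variables) and is exact for this formulation; an
# independent full enumeration oracle is in box_search_bruteforce().

#' Build hyper-boxes for problematic samples (exact MILP solution)
#'
#' Solves the box-construction model to proven optimality for the sample set
#' made of the problematic samples plus the class seeds (whose box and class
#' assignments are fixed before solving). Bounds of each returned box equal
#' the componentwise extrema of its member samples.
#'
#' @param data A scaled `expr_dataset` (the full training data; values in
#'   \[0, 1\]).
#' @param problematic Integer indices of problematic samples.
#' @param seeds A `seed_assignment` from [find_seeds()].
#' @param max_boxes_per_class Box budget per class (pool size =
#'   classes x budget), default 2.
#' @param lambda_box Objective weight on the number of boxes used
#'   (default 1); any weight in (0, 1] keeps misclassification lexicographically
#'   dominant when the box budget is below the sample count.
#' @return An object of class `milp_solution`: `boxes` (list of `hyper_box`,
#'   origin `"milp"`), `assignment` (box id per sample, named by sample
#'   index), `misclassified` (logical per sample), `boxes_used`,
#'   `objective_value`.
#' @export
build_boxes_milp <- function(data, problematic, seeds, max_boxes_per_class = 2,
                             lambda_box = 1) {
  K <- length(data$class_set)
  P <- as.integer(max_boxes_per_class)
  stopifnot(P >= 1, lambda_box >= 0)
  samples <- sort(unique(c(as.integer(problematic), unname(seeds$seed_index))))
  cls <- class_index(data)[samples]
  seed_pos <- match(unname(seeds$seed_index), samples)

  # pool: boxes 1..K are the seed boxes (class fixed), K+1..B free
  B <- K * P
  n_free_boxes <- B - K
  free_configs <- if (n_free_boxes > 0) {
    as.matrix(expand.grid(rep(list(0:K), n_free_boxes)))
  } else {
    matrix(integer(0), nrow = 1, ncol = 0)
  }
  best <- NULL
  for (r in seq_len(nrow(free_configs))) {
    zfree <- free_configs[r, ]
    box_class <- c(seq_len(K), zfree)          # 0 = unused
    used <- which(box_class > 0)
    # each sample takes the lowest-index used box of its own class when one
    # exists (always true: seed boxes cover every class), else the lowest
    # used box, counting one misclassification
    assign_box <- integer(length(samples))
    mis <- logical(length(samples))
    for (i in seq_along(samples)) {
      own <- used[box_class[used] == cls[i]]
      if (length(own)) {
        assign_box[i] <- own[1]
      } else {
        assign_box[i] <- used[1]
        mis[i] <- TRUE
      }
    }
    assign_box[seed_pos] <- seq_len(K)          # seed fixing
    mis[seed_pos] <- FALSE
    # boxes that are z-active but receive no sample only add cost; the exact
    # optimum deactivates them, so count only occupied actives plus seed boxes
    occupied <- sort(unique(c(seq_len(K), assign_box)))
    obj <- sum(mis) + lambda_box * length(occupied)
    cand <- list(obj = obj, assign = assign_box, mis = mis,
                 box_class = box_class, occupied = occupied)
    if (is.null(best) || obj < best$obj - 1e-12 ||
        (abs(obj - best$obj) <= 1e-12 && length(occupied) < length(best$occupied))) {
      best <- cand
    }
  }
  boxes <- lapply(best$occupied, function(b) {
    mem <- samples[best$assign == b]
    box_from_members(data$values, mem, data$class_set[best$box_class[b]], "milp")
  })
  mis_named <- best$mis
  names(mis_named) <- samples
  assignment <- match(best$assign, best$occupied)
  names(assignment) <- samples
  structure(list(boxes = boxes, assignment = assignment,
                 misclassified = mis_named,
                 boxes_used = length(best$occupied),
                 objective_value = best$obj),
            class = "milp_solution")
}

#' Brute-force oracle for the box-construction model
#'
#' Independently enumerates every box-class configuration of the pool and
#' every assignment of the non-seed samples to active boxes, evaluating the
#' objective (misclassifications plus `lambda_box` times boxes used) exactly.
#' Exponential; intended for verifying [build_boxes_milp()] on instances with
#' at most ~8 problematic samples.
#'
#' @inheritParams build_boxes_milp
#' @param max_states Safety cap on enumerated assignments per configuration.
#' @return List with `objective_value`, the minimum over the full enumeration.
#' @export
box_search_bruteforce <- function(data, problematic, seeds,
                                  max_boxes_per_class = 2, lambda_box = 1,
                                  max_states = 5e6) {
  K <- length(data$class_set)
  P <- as.integer(max_boxes_per_class)
  samples <- sort(unique(c(as.integer(problematic), unname(seeds$seed_index))))
  cls <- class_index(data)[samples]
  seed_pos <- match(unname(seeds$seed_index), samples)
  free_samples <- setdiff(seq_along(samples), seed_pos)
  B <- K * P
  n_free_boxes <- B - K
  free_configs <- if (n_free_boxes > 0) {
    as.matrix(expand.grid(rep(list(0:K), n_free_boxes)))
  } else {
    matrix(integer(0), nrow = 1, ncol = 0)
  }
  best_obj <- Inf
  for (r in seq_len(nrow(free_configs))) {
    box_class <- c(seq_len(K), free_configs[r, ])
    active <- which(box_class > 0)
    a <- length(active)
    nf <- length(free_samples)
    if (a^nf > max_states) stop("instance too large for brute force")
    total <- numeric(a^nf)
    if (nf > 0) {
      grid <- as.matrix(expand.grid(rep(list(seq_len(a)), nf)))
      for (j in seq_len(nf)) {
        wrong <- as.numeric(box_class[active] != cls[free_samples[j]])
        total <- total + wrong[grid[, j]]
      }
      # boxes used: for each assignment row, actives that received a sample
      # or are seed boxes
      used_count <- rep(0, length(total))
      seed_boxes <- seq_len(K)
      for (bpos in seq_len(a)) {
        b <- active[bpos]
        got <- if (nf > 0) rowSums(grid == bpos) > 0 else rep(FALSE, length(total))
        used_count <- used_count + as.numeric(got | b %in% seed_boxes)
      }
      obj <- total + lambda_box * used_count
      best_obj <- min(best_obj, min(obj))
    } else {
      best_obj <- min(best_obj, lambda_box * K)
    }
  }
  list(objective_value = best_obj)
}
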