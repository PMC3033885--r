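# Seed finding: one representative training sample per class, chosen by a
# pure integer program whose objective balances small in-class distances
# against large average out-class distances. The constraint matrix (one
# "exactly one seed per class" row per class over disjoint variable blocks)
# is totally unimodular, so the LP relaxation has integral basic optima and
# the IP decomposes into independent per-class minimizations.

# cost of choosing sample i as the seed of its own class:
# sum of distances to classmates minus the mean distance to all other samples
seed_costs <- function(data) {
  d <- as.matrix(stats::dist(data$values, method = "euclidean"))
  cls <- class_index(data)
  n <- length(cls)
  vapply(seq_len(n), function(i) {
    own <- cls == cls[i]
    n_out <- sum(!own)
    sum(d[i, own]) - if (n_out > 0) sum(d[i, !own]) / n_out else 0
  }, numeric(1))
}

#' Find one seed sample per class
#'
#' Solves the seed-finding integer program exactly: for each class the seed
#' minimizes (sum of Euclidean distances to its classmates) minus (the
#' average distance to all samples of other classes). Because the model
#' decomposes by class, per-class minimization is the provably optimal IP
#' solution; ties break to the lowest sample index.
#'
#' @param data A (scaled) `expr_dataset` with every class nonempty.
#' @return An object of class `seed_assignment`: list with `seed_index`
#'   (named integer vector, one sample index per class, `class_set` order)
#'   and `objective` (the summed optimal cost).
#' @export
find_seeds <- function(data) {
  if (any(!data$class_set %in% data$labels)) stop("every class must be nonempty")
  costs <- seed_costs(data)
  cls <- class_index(data)
  seeds <- vapply(seq_along(data$class_set), function(k) {
    idx <- which(cls == k)
    idx[which.min(costs[idx])]  # which.min takes the first = lowest index
  }, integer(1))
  names(seeds) <- data$class_set
  structure(list(seed_index = seeds,
                 objective = sum(costs[seeds])),
            class = "seed_assignment")
}

#' Brute-force oracle for seed finding
#'
#' Enumerates every combination of one candidate seed per class and evaluates
#' the seed objective exactly. Exponential in the class count; intended as the
#' independent check of [find_seeds()] on small instances.
#'
#' @param data A (scaled) `expr_dataset`.
#' @return As [find_seeds()] (first optimum in lexicographic sample-index
#'   order, matching the tie rule).
#' @export
seed_search_bruteforce <- function(data) {
  costs <- seed_costs(data)
  cls <- class_index(data)
  cand <- lapply(seq_along(data$class_set), function(k) which(cls == k))
  grid <- as.matrix(expand.grid(rev(cand)))[, length(cand):1, drop = FALSE]
  obj <- rowSums(matrix(costs[grid], nrow = nrow(grid)))
  best <- which.min(obj)
  seeds <- as.integer(grid[best, ])
  names(seeds) <- data$class_set
  structure(list(seed_index = seeds, objective = obj[best]),
            class = "seed_assignment")
}

#' Check LP-relaxation integrality of the seed model
#'
#' Solves the LP relaxation of the seed-finding model (minimize the seed
#' costs subject to one unit of seed mass per class, variables >= 0) with the
#' simplex method and reports whether the basic optimal solution is integral
#' and whether its value matches the IP optimum — the behaviour guaranteed by
#' the model's totally unimodular constraint set.
#'
#' @param data A (scaled) `expr_dataset`.
#' @param tol Integrality / value tolerance.
#' @return List with `integral`, `matches_ip`, `lp_value`, `ip_value`,
#'   `solution`.
#' @export
check_lp_integrality <- function(data, tol = 1e-7) {
  costs <- seed_costs(data)
  cls <- class_index(data)
  K <- length(data$class_set)
  n <- length(costs)
  A3 <- matrix(0, nrow = K, ncol = n)
  A3[cbind(cls, seq_len(n))] <- 1
  # boot::simplex needs non-negative... costs may be negative; shift so the
  # optimum is unaffected (adds a constant per class row)
  shift <- max(0, -min(costs)) + 1
  lp <- boot::simplex(a = costs + shift, A3 = A3, b3 = rep(1, K), maxi = FALSE)
  sol <- as.numeric(lp$soln)
  lp_value <- lp$value - K * shift
  ip <- find_seeds(data)
  integral <- all(abs(sol - round(sol)) < tol)
  list(integral = integral,
       matches_ip = abs(lp_value - ip$objective) < max(tol, tol * abs(ip$objective)),
       lp_value = lp_value, ip_value = ip$objective, solution = sol)
}
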