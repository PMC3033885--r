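test_that("F CDF matches quadrature, symmetry, and limits", {
  expect_equal(f_cdf(0, 3, 7), 0)
  expect_equal(f_cdf(1, 6, 6), 0.5, tolerance = 1e-12)  # F(v,v): P(F<=1)=0.5
  expect_equal(f_cdf(3.0, 5, 10), 0.934442437906156, tolerance = 1e-9)
  expect_error(f_cdf(1, 0, 5), "positive")
  expect_error(f_cdf(-1, 2, 5), "non-negative")
  # reflection identity F(x; v1, v2) = 1 - F(1/x; v2, v1)
  for (x in c(0.2, 1, 2.5)) {
    expect_equal(f_cdf(x, 4, 9), 1 - f_cdf(1 / x, 9, 4), tolerance = 1e-12)
  }
})

test_that("variance-ratio scores mark class-tight genes as informative", {
  set.seed(21)
  n <- 30
  labels <- rep(c("A", "B", "C"), each = 10)
  # gene 1: tight in class A, spread elsewhere; gene 2: pure noise
  g1 <- c(rnorm(10, 5, 0.01), rnorm(10, 8, 1), rnorm(10, 2, 1))
  g2 <- rnorm(n)
  d <- tiny_dataset(cbind(g1, g2), labels)
  tab <- fcdf_scores(d)
  expect_equal(dim(tab$scores), c(2L, 3L))
  expect_true(all(tab$scores >= 0 & tab$scores <= 1))
  expect_gt(tab$scores[1, "A"], 0.99)       # informative orientation: near 1
  expect_gt(tab$summary[1], tab$summary[2])
  # a variance ratio of exactly 1 gives the F CDF evaluated at 1
  same <- tiny_dataset(cbind(rep(c(0, 1), 8)), rep(c("A", "B"), each = 8))
  tab1 <- fcdf_scores(same)
  ratio <- stats::var(same$values[, 1]) /
    stats::var(same$values[same$labels == "A", 1])
  expect_equal(tab1$scores[1, "A"], f_cdf(ratio, 15, 7), tolerance = 1e-12)
  expect_error(fcdf_scores(tiny_dataset(cbind(1:4), c("A", "A", "A", "B"))),
               ">= 2 samples")
  # null genes score mid-range, not at the extremes
  meds <- numeric(20)
  for (s in 1:20) {
    set.seed(s)
    dn <- tiny_dataset(matrix(rnorm(200 * 5), 200),
                       rep(c("A", "B"), each = 100))
    meds[s] <- stats::median(fcdf_scores(dn)$summary)
  }
  expect_gt(stats::median(meds), 0.2)
  expect_lt(stats::median(meds), 0.8)
})

test_that("zero within-class variance is floored with a warning", {
  d <- tiny_dataset(cbind(c(1, 1, 1, 5, 9, 2)),
                    rep(c("A", "B"), each = 3))
  expect_warning(tab <- fcdf_scores(d), "zero variance")
  expect_gt(tab$scores[1, "A"], 0.99)
})

test_that("redundancy filter drops correlated genes in rank order", {
  set.seed(5)
  base <- rnorm(40)
  vals <- cbind(base, base, base + rnorm(40, 0, 1.5), rnorm(40))
  d <- tiny_dataset(vals, rep(c("A", "B"), 20))
  expect_equal(redundancy_filter(1:4, d, 0.9), c(1L, 3L, 4L))
  # threshold 1: only exact duplicates go
  expect_equal(redundancy_filter(1:4, d, 1.0), c(1L, 3L, 4L))
  vals2 <- cbind(base, base * 0.99 + rnorm(40, 0, 0.001), rnorm(40))
  d2 <- tiny_dataset(vals2, rep(c("A", "B"), 20))
  expect_equal(redundancy_filter(1:3, d2, 1.0), 1:3)
  # independent genes survive untouched
  set.seed(6)
  d3 <- tiny_dataset(matrix(rnorm(50 * 6), 50), rep(c("A", "B"), 25))
  expect_equal(redundancy_filter(1:6, d3, 0.9), 1:6)
  # kept set is pairwise below threshold
  kept <- redundancy_filter(1:4, d, 0.9)
  cors <- abs(stats::cor(d$values[, kept]))
  diag(cors) <- 0
  expect_true(all(cors <= 0.9))
})

test_that("gene-set search trades noise genes for planted markers", {
  # moderate effect size: full accuracy needs most of the planted markers,
  # so the swap trajectory is visible before the accuracy ceiling
  sim <- make_microarray(seed = 303, effect_size = 1)
  rk <- rank_genes(sim$data, "infogain", top_n = 30)
  noise_pool <- setdiff(seq_len(500), sim$planted)
  initial <- noise_pool[1:5]
  trace <- optimal_gene_set_search(sim$data, initial_set = initial,
                                   pool = rk$genes, max_iter = 10,
                                   cv_spec = list(k = 5, repeats = 1),
                                   seed = 303)
  expect_gte(sum(sim$planted %in% trace$best_set), 4)
  expect_gte(trace$best_accuracy, trace$iterations$accuracy[1])
  # the best accuracy is the max of the trace (ties to earliest iteration)
  expect_equal(trace$best_accuracy, max(trace$iterations$accuracy))
  first_best <- which(trace$iterations$accuracy == trace$best_accuracy)[1]
  expect_identical(trace$best_set, trace$sets[[first_best]])
  expect_false(anyDuplicated(trace$best_set) > 0)
})

test_that("search degenerate cases: no iterations, exhausted pool", {
  d <- make_separable(n_classes = 2, n_per_class = 6, n_genes = 4, seed = 7)
  t0 <- optimal_gene_set_search(d, initial_set = 1:2, pool = 1:4,
                                max_iter = 0, cv_spec = list(k = 3, repeats = 1))
  expect_equal(nrow(t0$iterations), 1L)
  t1 <- optimal_gene_set_search(d, initial_set = 1:4, pool = 1:4,
                                max_iter = 5, cv_spec = list(k = 3, repeats = 1))
  expect_equal(nrow(t1$iterations), 1L)  # pool == initial set: nothing unused
  expect_error(optimal_gene_set_search(d, initial_set = c(1, 1), pool = 1:4),
               "duplicates")
})
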