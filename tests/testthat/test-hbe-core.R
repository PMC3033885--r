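test_that("class bounds are the componentwise extrema", {
  d <- tiny_dataset(rbind(c(0, 0), c(1, 1), c(0.4, 0.2)), c("A", "A", "B"))
  cb <- class_bounds(d)
  expect_equal(cb$A$lower, c(0, 0))
  expect_equal(cb$A$upper, c(1, 1))
  expect_equal(cb$B$lower, cb$B$upper)  # singleton class: point box
})

test_that("box overlap uses the closed-interval convention", {
  b1 <- hyper_box("A", c(0, 0), c(1, 1))
  expect_false(boxes_overlap(b1, hyper_box("B", c(2, 0), c(3, 1))))
  expect_true(boxes_overlap(b1, hyper_box("B", c(1, 0.5), c(2, 1.5))))  # shared face
  expect_true(boxes_overlap(b1, b1))
  expect_error(boxes_overlap(b1, hyper_box("B", 0, 1)), "dimensionality")
})

test_that("Euclidean distance behaves", {
  expect_equal(pairwise_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(pairwise_distance(1:3, 1:3), 0)
  set.seed(1)
  a <- rnorm(4); b <- rnorm(4)
  expect_equal(pairwise_distance(a, b), pairwise_distance(b, a))
  expect_error(pairwise_distance(1:2, 1:3), "length")
})

test_that("problematic detection marks foreign-box members and refines", {
  sep <- tiny_dataset(cbind(c(0, 0.1, 0.9, 1)), c("A", "A", "B", "B"))
  expect_length(detect_problematic(sep)$problematic, 0)
  ovl <- tiny_dataset(cbind(c(0, 0.5, 0.4, 1)), c("A", "A", "B", "B"))
  p <- detect_problematic(ovl, max_rounds = 0)
  expect_setequal(p$problematic, c(2L, 3L))
  same <- tiny_dataset(cbind(c(0.3, 0.3, 0.3, 0.3)), c("A", "A", "B", "B"))
  expect_length(detect_problematic(same)$non_problematic, 0)
  # refinement rounds shrink the problematic set monotonically
  set.seed(8)
  f <- make_fig2_scenario(n_per_class = 15, overlap_fraction = 0.3, seed = 8)
  p0 <- detect_problematic(f, max_rounds = 0)
  p2 <- detect_problematic(f, max_rounds = 2)
  expect_true(all(p2$problematic %in% p0$problematic))
  expect_lte(length(p2$problematic), length(p0$problematic))
})

test_that("seed IP matches exhaustive enumeration and decomposes by class", {
  # singleton classes: each sample is its own seed
  d1 <- tiny_dataset(rbind(c(0, 0), c(1, 1)), c("A", "B"))
  expect_equal(unname(find_seeds(d1)$seed_index), c(1L, 2L))
  # 1-D hand instance: enumerate the objective exactly
  d2 <- tiny_dataset(cbind(c(0, 0.1, 0.2, 10)), c("A", "A", "A", "B"))
  costs <- sapply(1:3, function(i) {
    sum(abs(d2$values[i, 1] - d2$values[1:3, 1])) - abs(d2$values[i, 1] - 10)
  })
  expect_equal(unname(find_seeds(d2)$seed_index[1]), which.min(costs))
  # random instances against the brute-force oracle
  for (s in 1:30) {
    inst <- random_instance(s)
    ip <- find_seeds(inst)
    bf <- seed_search_bruteforce(inst)
    expect_equal(ip$objective, bf$objective, tolerance = 1e-9)
    expect_identical(ip$seed_index, bf$seed_index)
  }
})

test_that("seed model LP relaxation has an integral basic optimum", {
  for (s in c(1, 2, 3, 17, 23)) {
    rep <- check_lp_integrality(random_instance(s))
    expect_true(rep$integral)
    expect_true(rep$matches_ip)
  }
})

test_that("MILP box construction is optimal and respects seed fixing", {
  # separable 1-D classes, one box each: no misclassification
  d <- tiny_dataset(cbind(c(0, 0.1, 0.9, 1)), c("A", "A", "B", "B"))
  sc <- apply_scaler(d, fit_scaler(d))
  seeds <- find_seeds(sc)
  sol <- build_boxes_milp(sc, problematic = 1:4, seeds = seeds,
                          max_boxes_per_class = 1, lambda_box = 0.5)
  expect_equal(sol$objective_value, 2 * 0.5)
  expect_equal(sol$boxes_used, 2)
  expect_false(any(sol$misclassified))
  # identical points with different labels: the model still assigns each
  # point to its own class's box (overlap is allowed at this stage and
  # resolved later by intersection elimination)
  di <- tiny_dataset(cbind(c(0.5, 0.5), c(0.5, 0.5)), c("A", "B"))
  ssi <- find_seeds(di)
  soli <- build_boxes_milp(di, problematic = 1:2, seeds = ssi,
                           max_boxes_per_class = 1)
  expect_equal(sum(soli$misclassified), 0)
  expect_equal(soli$objective_value, 2)
  # oracle equivalence on random instances
  for (s in 1:15) {
    set.seed(s)
    inst <- random_instance(s, n_classes = 2, per_class_max = 5, genes = 2)
    scd <- apply_scaler(inst, fit_scaler(inst))
    sds <- find_seeds(scd)
    prob <- utils::head(seq_len(n_samples(scd)), 8)
    a <- build_boxes_milp(scd, prob, sds, max_boxes_per_class = 2)
    b <- box_search_bruteforce(scd, prob, sds, max_boxes_per_class = 2)
    expect_equal(a$objective_value, b$objective_value, tolerance = 1e-9)
  }
})

test_that("non-problematic enclosure builds one defined box per occupied class", {
  d <- tiny_dataset(rbind(c(0, 0), c(0.2, 0.1), c(0.9, 0.9)),
                    c("A", "A", "B"))
  boxes <- enclose_nonproblematic(d, 1:3)
  expect_length(boxes, 2)
  expect_equal(boxes[[1]]$upper, c(0.2, 0.1))
  expect_equal(boxes[[2]]$lower, boxes[[2]]$upper)
  expect_length(enclose_nonproblematic(d, 1:2), 1)  # class B absent
})

test_that("intersection elimination follows the deterministic split rule", {
  # 1-D: defined box A = [0, 0.6] vs milp box B = [0.5, 1]
  vals <- matrix(c(0, 0.3, 0.6, 0.5, 1), ncol = 1)
  boxes <- list(
    hyperbox:::box_from_members(vals, 1:3, "A", "defined"),
    hyperbox:::box_from_members(vals, 4:5, "B", "milp")
  )
  out <- eliminate_intersections(boxes, vals, class_set = c("A", "B"))
  expect_equal(cross_class_overlaps(out), 0)
  # member 0.6 was shed from A first: A shrank to [0, 0.3]
  boxA <- Filter(function(b) b$class_label == "A" && b$origin == "defined", out)
  expect_equal(boxA[[1]]$upper, 0.3)
  # every sample still lives in a box of its own class
  for (i in 1:5) {
    own <- vapply(out, function(b) i %in% b$members, logical(1))
    expect_true(any(own))
  }
  # non-overlapping input comes back unchanged
  clean <- list(hyper_box("A", 0, 0.3, members = 1L),
                hyper_box("B", 0.7, 1, members = 4L))
  expect_identical(eliminate_intersections(clean, vals), clean)
  # identical cross-class point boxes are inconsistent data
  same <- matrix(c(0.5, 0.5), ncol = 1)
  dup <- list(hyperbox:::box_from_members(same, 1L, "A", "defined"),
              hyperbox:::box_from_members(same, 2L, "B", "defined"))
  expect_error(eliminate_intersections(dup, same), "inconsistent")
})

test_that("fitting separable data gives one box per class with no flags", {
  d <- make_separable(n_classes = 3, n_per_class = 8, seed = 4)
  m <- hbe_fit(d)
  expect_length(m$boxes, 3)
  expect_false(any(m$training_flags))
  expect_equal(predict(m, d$values), d$labels)
})

test_that("fit handles overlap: many boxes, full training accuracy, no cross-class overlap", {
  f <- make_fig2_scenario(n_per_class = 12, overlap_fraction = 0.2, seed = 5)
  m <- hbe_fit(f)
  expect_gte(length(m$boxes), 4)
  geo <- check_model_geometry(m, f)
  expect_equal(geo$n_overlap, 0)
  expect_true(geo$bounds_ok)
  expect_true(geo$all_covered)
  expect_equal(predict(m, f$values)[!m$training_flags],
               f$labels[!m$training_flags])
  # single-gene overlapping two-class data forces a split (>= 3 boxes)
  o <- tiny_dataset(cbind(c(0, 0.3, 0.6, 0.5, 0.8, 1)),
                    c("A", "A", "A", "B", "B", "B"))
  expect_gte(length(hbe_fit(o)$boxes), 3)
})

test_that("fitting is deterministic", {
  f <- make_fig2_scenario(n_per_class = 10, overlap_fraction = 0.3, seed = 9)
  m1 <- hbe_fit(f)
  m2 <- hbe_fit(f)
  m1$partition <- m2$partition <- NULL
  expect_identical(m1, m2)
})

test_that("prediction uses containment, nearest box, then the tie rules", {
  model <- structure(list(
    scaler = structure(list(min = 0, max = 1, gene_ids = "g1"),
                       class = "hbe_scaler"),
    selected_genes = "g1", class_set = c("A", "B"),
    boxes = list(hyper_box("A", 0, 0.2, members = 1L),
                 hyper_box("B", 0.8, 1, members = 2L)),
    training_flags = c(FALSE, FALSE)), class = "hbe_model")
  expect_equal(predict(model, matrix(0.1), raw = FALSE), "A")   # containment
  expect_equal(predict(model, matrix(0.3), raw = FALSE), "A")   # nearer box
  expect_equal(predict(model, matrix(0.5), raw = FALSE), "A")   # tie: class order
  expect_equal(predict(model, matrix(0.95), raw = FALSE), "B")
  expect_error(predict(model, matrix(1, 1, 2), raw = FALSE), "genes")
})

test_that("models serialize to JSON and back without behavioral change", {
  d <- make_separable(seed = 12)
  m <- hbe_fit(d)
  f <- withr::local_tempfile(fileext = ".json")
  write_hbe_model(m, f)
  m2 <- read_hbe_model(f)
  expect_equal(predict(m2, d$values), predict(m, d$values))
  expect_equal(m2$selected_genes, m$selected_genes)
  expect_equal(length(m2$boxes), length(m$boxes))
})
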