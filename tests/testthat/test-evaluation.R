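test_that("trapezoid_membership reproduces the worked examples", {
  expect_identical(trapezoid_membership(150, 50, 100, 200, 250), 1)
  expect_identical(trapezoid_membership(40, 50, 100, 200, 250), 0)
  expect_equal(trapezoid_membership(75, 50, 100, 200, 250), 0.5)
  expect_identical(trapezoid_membership(6000, 0, 5000, 7000, 8000), 1)
  expect_identical(trapezoid_membership(8500, 0, 5000, 7000, 8000), 0)
})

test_that("trapezoid_membership handles edges and degenerate sides", {
  # boundary conventions of the piecewise definition
  expect_equal(trapezoid_membership(50, 50, 100, 200, 250), 0)
  expect_equal(trapezoid_membership(100, 50, 100, 200, 250), 1)
  expect_equal(trapezoid_membership(250, 50, 100, 200, 250), 0)
  # coincident edges: plateau value wins
  expect_equal(trapezoid_membership(5, 5, 5, 9, 9), 1)
  expect_equal(trapezoid_membership(9, 5, 5, 9, 9), 1)
  expect_error(trapezoid_membership(1, 3, 2, 4, 5), "edges")

  # monotone up to the plateau, monotone down after it, bounded
  f <- seq(0, 300, by = 1)
  th <- trapezoid_membership(f, 50, 100, 200, 250)
  expect_true(all(th >= 0 & th <= 1))
  expect_true(all(diff(th[f <= 100]) >= 0))
  expect_true(all(diff(th[f >= 200]) <= 0))
})

test_that("match_objects pairs greedily by overlap", {
  m <- matrix(0L, 6, 6); m[2:3, 2:3] <- 1L; m[5:6, 5:6] <- 2L
  self <- match_objects(m, m)
  expect_equal(self$pred, self$gt)
  expect_equal(self$overlap, c(4L, 4L))

  disj <- matrix(0L, 6, 6); disj[1, 1] <- 1L
  expect_equal(nrow(match_objects(disj, m * 0L)), 0)

  # one prediction spanning two ground-truth objects goes to the larger
  gt <- matrix(0L, 4, 8); gt[, 1:3] <- 1L; gt[, 5:8] <- 2L
  pred <- matrix(0L, 4, 8); pred[, 2:7] <- 1L
  mm <- match_objects(pred, gt)
  expect_equal(nrow(mm), 1)
  expect_equal(mm$gt, 2L)
  expect_equal(mm$overlap, 12L)

  expect_error(match_objects(pred, gt[, -1]), "shape")
})

test_that("quality_Q implements the three fuzzified measures", {
  gt_lab <- matrix(0L, 10, 22)
  gt_lab[1:10, 1:10] <- 1L; gt_lab[1:10, 13:22] <- 2L
  gt <- ground_truth(gt_lab, c(1L, 2L))

  # identical prediction with correct classes
  rep1 <- quality_Q(gt_lab, c(1L, 2L), gt)
  expect_identical(rep1$Q, 1)
  expect_equal(c(rep1$q1, rep1$q2, rep1$q3), c(0, 0, 0))

  # empty prediction: mu2 = 0 hence Q = 0
  rep0 <- quality_Q(matrix(0L, 10, 22), integer(0), gt)
  expect_identical(rep0$Q, 0)
  expect_equal(rep0$mu2, 0)

  # one of two 100-pixel objects found exactly, correct class
  pred <- gt_lab; pred[pred == 2L] <- 0L
  rep2 <- quality_Q(pred, 1L, gt)
  expect_equal(c(rep2$q1, rep2$q2, rep2$q3), c(0.5, 0.5, 0))
  expect_equal(rep2$Q, 0.25)

  # Q is exactly the product of the memberships
  expect_identical(rep2$Q, rep2$mu1 * rep2$mu2 * rep2$mu3)

  # wrong class on the matched object flips mu3 to 0
  rep3 <- quality_Q(pred, 2L, gt)
  expect_equal(rep3$q3, 1)
  expect_equal(rep3$Q, 0)

  # empty ground truth conventions
  gt_empty <- ground_truth(matrix(0L, 4, 4), integer(0))
  expect_equal(quality_Q(matrix(0L, 4, 4), integer(0), gt_empty)$Q, 1)
  some <- matrix(0L, 4, 4); some[1:2, 1:2] <- 1L
  expect_equal(quality_Q(some, 1L, gt_empty)$Q, 0)
})

test_that("quality_Q is invariant under object relabeling", {
  set.seed(17)
  sc <- render_scene(default_scene(size = 96))
  img <- apply_artifacts(sc$image, 4, 5, seed = 3)
  pred <- run_pipeline(img, c(1, 0.5, 1), "manual_threshold")
  n <- max(pred)
  perm <- sample(n)
  relab <- pred; relab[pred > 0] <- perm[pred[pred > 0]]
  cls <- rep(1L, n)
  q1 <- quality_Q(pred, cls, sc$gt)
  q2 <- quality_Q(relab, cls[order(perm)], sc$gt)
  expect_equal(q1$Q, q2$Q)
  expect_equal(q1$q2, q2$q2)
})

test_that("robustness_R is the arithmetic mean, bit-exact", {
  expect_identical(robustness_R(rep(1, 13)), 1)
  expect_identical(robustness_R(c(1, 0.5, 0)), 0.5)
  set.seed(2)
  q <- runif(13)
  expect_identical(robustness_R(q), sum(q) / 13)
  expect_identical(robustness_R(q), robustness_R(rev(q)))
  expect_error(robustness_R(numeric(0)), "empty")
})

test_that("quality_feat follows the fuzzy sum formula", {
  spec <- fuzzy_spec(features = list(area = c(0, 10, 20, 30)),
                     count = c(0, 0, 100, 200))
  one <- data.frame(id = 1, area = 15)
  expect_identical(quality_feat(one, spec), 1)

  expect_identical(quality_feat(one[0, ], spec), 0)

  two <- data.frame(id = 1:2, area = c(15, 25))  # products 1 and 0.5
  expect_equal(quality_feat(two, spec), 0.75)

  # count term scales the sum
  spec_c <- fuzzy_spec(features = list(area = c(0, 10, 20, 30)),
                       count = c(0, 4, 4, 8))
  expect_equal(quality_feat(two, spec_c),
               trapezoid_membership(2, 0, 4, 4, 8) * 0.75)

  # known n_c: top-n_c products summed, still normalized by n_t
  spec_n <- fuzzy_spec(features = list(area = c(0, 10, 20, 30)), n_c = 2)
  six <- data.frame(id = 1:6, area = c(15, 15, 12, 40, 50, 60))
  expect_equal(quality_feat(six, spec_n), 2 / 6)
})

test_that("setscrew_spec derives edges from the clean ground truth", {
  sc <- render_scene(default_scene(size = 96))
  spec <- setscrew_spec(sc$gt)
  abar <- mean(extract_features(sc$gt$labels)$area[sc$gt$classes == 1])
  expect_equal(spec$features$area, abar / 6000 * c(0, 5000, 7000, 8000))
  expect_equal(spec$n_c, 4L)
  # ground-truth capsules score product 1 under their own spec
  rec <- extract_features(sc$gt$labels)
  prods <- adaptseg:::fuzzy_products(rec, spec)
  expect_true(all(prods[sc$gt$classes == 1] == 1))
  expect_true(all(prods[sc$gt$classes != 1] == 0))
})
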