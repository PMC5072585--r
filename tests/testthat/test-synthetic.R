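test_that("render_scene draws what the spec says", {
  empty <- scene_spec(list(), width = 32L, height = 32L, background = 0.3)
  sc <- render_scene(empty)
  expect_true(all(sc$image == 0.3))
  expect_equal(length(sc$gt$classes), 0)

  one <- scene_spec(list(scene_object("rectangle", class = 1, center = c(16, 16),
                                      size = c(11, 11), intensity = 0.9)),
                    width = 32L, height = 32L, background = 0.1)
  sc <- render_scene(one)
  expect_equal(sum(sc$gt$labels == 1), 121)
  expect_equal(max(sc$gt$labels), 1)
  expect_true(all(sc$image[sc$gt$labels == 1] == 0.9))
  expect_true(all(sc$image[sc$gt$labels == 0] == 0.1))

  # 4 disks of class 1 and 3 rectangles of class 2
  mk_disk <- function(r, c) scene_object("disk", 1, c(r, c), 4, 0.8)
  mk_rect <- function(r, c) scene_object("rectangle", 2, c(r, c), c(7, 7), 0.7)
  objs <- list(mk_disk(12, 12), mk_disk(12, 36), mk_disk(36, 12),
               mk_disk(36, 36), mk_rect(24, 24), mk_rect(12, 60),
               mk_rect(36, 60))
  sc <- render_scene(scene_spec(objs, width = 72L, height = 48L))
  expect_equal(max(sc$gt$labels), 7)
  expect_equal(sum(sc$gt$classes == 1), 4)
  expect_equal(sum(sc$gt$classes == 2), 3)
})

test_that("render_scene rejects invalid layouts", {
  overlap <- scene_spec(list(
    scene_object("disk", 1, c(16, 16), 6, 0.8),
    scene_object("disk", 1, c(18, 18), 6, 0.8)), width = 32L, height = 32L)
  expect_error(render_scene(overlap), "overlap")

  outside <- scene_spec(list(scene_object("disk", 1, c(3, 16), 6, 0.8)),
                        width = 32L, height = 32L)
  expect_error(render_scene(outside), "border")

  expect_error(scene_spec(list(scene_object("disk", 2, c(16, 16), 4, 0.8)),
                          width = 32L, height = 32L),
               "class")
})

test_that("apply_artifacts degrades as stated", {
  sc <- render_scene(two_level_scene())
  img <- sc$image

  expect_identical(apply_artifacts(img, 1, 1, seed = 9), img)

  # pure noise on a constant image: mean close to 0.5 (law of large numbers)
  const <- matrix(0.5, 64, 64)
  noisy <- apply_artifacts(const, 1, 14, seed = 2)
  expect_lt(abs(mean(noisy) - 0.5), 3 * 0.25 / sqrt(length(const)))
  expect_true(all(noisy >= 0 & noisy <= 1))

  # pure shading: dividing out the clean image recovers the analytic ramp
  shaded <- apply_artifacts(img, 13, 1, seed = 2)
  h <- nrow(img); w <- ncol(img)
  ramp <- (matrix(seq_len(h) - 1, h, w) +
             matrix(seq_len(w) - 1, h, w, byrow = TRUE)) / (h - 1 + w - 1)
  expect_equal(shaded / img, 1 - 0.6 * ramp, tolerance = 1e-12)

  expect_error(apply_artifacts(img, 0, 1), "range")
  expect_error(apply_artifacts(img, 1, 15), "range")

  # determinism and substream independence
  expect_identical(apply_artifacts(img, 5, 7, seed = 3),
                   apply_artifacts(img, 5, 7, seed = 3))
  expect_false(identical(apply_artifacts(img, 5, 7, seed = 3),
                         apply_artifacts(img, 5, 7, seed = 4)))
})

test_that("artifact_level is calibrated, bounded and monotone", {
  sc <- render_scene(two_level_scene())
  img <- sc$image
  norm <- calibrate_artifact_norm(img, seed = 5)

  expect_equal(artifact_level(img, img, norm), 0)
  worst <- apply_artifacts(img, 13, 14, seed = 5)
  expect_equal(artifact_level(img, worst, norm), 1)

  A <- vapply(1:13, function(b)
    artifact_level(img, apply_artifacts(img, b, b + 1, seed = 5), norm),
    numeric(1))
  expect_true(all(diff(A) > 0))
  expect_true(all(A >= 0 & A <= 1))

  expect_error(artifact_level(img, img[-1, ]), "dimensions")
})

test_that("artifact level increases with b at fixed n and vice versa", {
  sc <- render_scene(two_level_scene())
  img <- sc$image
  norm <- calibrate_artifact_norm(img, seed = 1)
  A_b <- vapply(c(1, 5, 9, 13), function(b)
    artifact_level(img, apply_artifacts(img, b, 6, seed = 1), norm),
    numeric(1))
  expect_true(all(diff(A_b) > 0))
  A_n <- vapply(c(1, 5, 10, 14), function(n)
    artifact_level(img, apply_artifacts(img, 6, n, seed = 1), norm),
    numeric(1))
  expect_true(all(diff(A_n) > 0))
})

test_that("generate_series meets its contract", {
  spec <- default_scene(size = 96)
  ser <- generate_series(spec)
  expect_equal(length(ser$images), 13)
  expect_equal(ser$levels$n, ser$levels$b + 1L)
  expect_true(all(diff(ser$levels$A) > 0))
  expect_equal(ser$levels$A[13], 1)
  expect_true(all(vapply(ser$images, function(im) all(im >= 0 & im <= 1),
                         logical(1))))

  # ground truth matches the spec
  expect_equal(length(ser$gt$classes), length(spec$objects))
  expect_equal(as.vector(table(ser$gt$classes)), c(4, 2, 2))

  # degenerate single-level series at (1, 2)
  s1 <- generate_series(spec, B = 1, N = 14)
  expect_equal(length(s1$images), 1)
  expect_identical(s1$images[[1]],
                   apply_artifacts(s1$clean, 1, 2, B = 1, N = 14,
                                   seed = spec$seed))

  expect_error(generate_series(spec, B = 14, N = 14), "B <= N - 1")
})

test_that("series generation is bit-reproducible in seed", {
  a <- generate_series(default_scene(size = 96, seed = 5))
  b <- generate_series(default_scene(size = 96, seed = 5))
  c <- generate_series(default_scene(size = 96, seed = 6))
  expect_identical(a$images, b$images)
  expect_identical(a$levels, b$levels)
  expect_false(identical(a$images[[5]], c$images[[5]]))
})
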