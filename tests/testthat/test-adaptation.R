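test_that("param_grid validates bounds and step", {
  g <- param_grid(t_min = 0.1, t_max = 0.5, delta = 0.1)
  expect_equal(g$t, seq(0.1, 0.5, by = 0.1))
  expect_error(param_grid(t_min = 0.5, t_max = 0.1, delta = 0.1), "t_min")
  expect_error(param_grid(t_min = 0.1, t_max = 0.5, delta = 0.5), "delta")
  expect_error(param_grid(t_min = 0.1, t_max = 0.5, delta = 0), "delta")
  expect_error(param_grid(w = 2, t = 0.5), "odd")
  expect_error(param_grid(t = 1.5), "\\[0, 1\\]")
  g3 <- param_grid(w = c(1, 3), t = c(0.2, 0.4), s = c(1, 3))
  expect_equal(nrow(g3), 8)
})

test_that("adapt_per_image finds perfect parameters on a separable scene", {
  sc <- render_scene(two_level_scene())
  crit <- criterion_quality(sc$gt)
  grid <- param_grid(t_min = 0.1, t_max = 0.78, delta = 0.02)
  res <- adapt_per_image(sc$image, "manual_threshold", grid, crit)
  expect_identical(res$value, 1)
  # thresholding is strict >, so t = 0.2 already separates the levels; the
  # smallest-t tie rule therefore returns the closed lower band edge
  expect_gte(res$p_opt[["t"]], 0.2)
  expect_lt(res$p_opt[["t"]], 0.8)

  single <- param_grid(t = 0.5)
  res1 <- adapt_per_image(sc$image, "manual_threshold", single, crit)
  expect_equal(unname(res1$p_opt), c(1, 0.5, 1))
})

test_that("adapt results are bit-identical to an exhaustive double loop", {
  ser <- tiny_series(B = 3)
  crit <- criterion_quality(ser$gt)
  grid <- param_grid(w = c(1, 3), t = seq(0.2, 0.65, by = 0.05), s = 1)
  expect_equal(nrow(grid), 20)

  vals <- brute_force_adapt(ser$images, "otsu", grid, crit)

  for (j in 1:3) {
    res <- adapt_per_image(ser$images[[j]], "otsu", grid, crit)
    i_star <- brute_force_argmax(grid, vals[, j])
    expect_identical(res$value, vals[i_star, j])
    expect_identical(unname(res$p_opt),
                     unname(c(grid$w[i_star], grid$t[i_star], grid$s[i_star])))
    expect_identical(res$trace$value, vals[, j])
  }

  rob <- adapt_robust(ser, "otsu", grid, crit)
  R <- rowSums(vals) / ncol(vals)
  i_star <- brute_force_argmax(grid, R)
  expect_identical(rob$value, R[i_star])
  expect_identical(unname(rob$p_opt),
                   unname(c(grid$w[i_star], grid$t[i_star], grid$s[i_star])))
})

test_that("adapt_robust reduces to per-image adaptation on identical images", {
  sc <- render_scene(two_level_scene())
  fake <- list(images = list(sc$image, sc$image, sc$image))
  crit <- criterion_quality(sc$gt)
  grid <- param_grid(t_min = 0.1, t_max = 0.7, delta = 0.1)
  rob <- adapt_robust(fake, "manual_threshold", grid, crit)
  per <- adapt_per_image(sc$image, "manual_threshold", grid, crit)
  expect_identical(rob$p_opt, per$p_opt)
  expect_identical(rob$value, per$value)
})

test_that("ties break to smallest t, then w, then s", {
  # an all-background image scores identically at every grid point
  flat <- matrix(0.1, 24, 24)
  gt <- ground_truth(matrix(0L, 24, 24), integer(0))
  crit <- criterion_quality(gt)
  grid <- param_grid(w = c(3, 1), t = c(0.6, 0.4), s = c(5, 1))
  res <- adapt_per_image(flat, "manual_threshold", grid, crit)
  expect_equal(unname(res$p_opt), c(1, 0.4, 1))
})

test_that("best_of never falls below the feedforward baseline", {
  ff <- list(value = 0.3); fb <- list(value = 0.7)
  expect_equal(best_of(ff, fb)$chosen, "feedback")
  expect_equal(best_of(list(value = 0.5), list(value = 0.5))$chosen,
               "feedback")
  expect_equal(best_of(list(value = 0.9), list(value = 0.2))$value, 0.9)

  ser <- tiny_series(B = 3)
  crit <- criterion_quality(ser$gt)
  grid <- param_grid(t_min = 0.3, t_max = 0.6, delta = 0.1)
  for (img in ser$images) {
    std <- adaptseg:::feedforward_result(img, "otsu", crit)
    auto <- adapt_per_image(img, "otsu", grid, crit)
    expect_gte(best_of(std, auto)$value, std$value)
    expect_gte(best_of(std, auto)$value, auto$value)
  }
})

test_that("enlarging the grid never decreases the achieved criterion", {
  ser <- tiny_series(B = 2)
  crit <- criterion_quality(ser$gt)
  small <- param_grid(t = seq(0.2, 0.6, by = 0.1))
  big <- param_grid(w = c(1, 3), t = seq(0.2, 0.6, by = 0.05), s = c(1, 3))
  for (img in ser$images) {
    v_small <- adapt_per_image(img, "manual_threshold", small, crit)$value
    v_big <- adapt_per_image(img, "manual_threshold", big, crit)$value
    expect_gte(v_big, v_small)
  }
})

test_that("delta_sweep is non-increasing over nested aligned grids", {
  ser <- tiny_series(B = 4)
  sw <- delta_sweep(ser, "otsu", c(0.04, 0.08, 0.16), 0.1, 0.74)
  expect_equal(sw$delta, c(0.04, 0.08, 0.16))
  expect_true(all(diff(sw$R) <= 1e-12))
})

test_that("adaptation recovers a threshold inside the intensity band", {
  sc <- render_scene(two_level_scene())  # objects 0.8 on background 0.2
  crit <- criterion_quality(sc$gt)
  grid <- param_grid(t_min = 0.1, t_max = 0.78, delta = 0.02)

  per <- adapt_per_image(sc$image, "manual_threshold", grid, crit)
  expect_identical(per$value, 1)
  expect_true(per$p_opt[["t"]] >= 0.2 && per$p_opt[["t"]] < 0.8)

  flat_series <- list(images = rep(list(sc$image), 3))
  rob <- adapt_robust(flat_series, "manual_threshold", grid, crit)
  expect_identical(rob$value, 1)
  expect_true(rob$p_opt[["t"]] >= 0.2 && rob$p_opt[["t"]] < 0.8)
})

test_that("case experiments emit coherent tables on a short series", {
  ser <- tiny_series(B = 2, size = 96)
  res <- case1_experiment(ser, robust = FALSE,
                          multi_t = list(t_min = 0.05, t_max = 0.85,
                                         delta = 0.1),
                          multi_s = c(3L, 5L))
  expect_equal(nrow(res$per_image), 4)
  expect_true(all(res$per_image$Q_best >= res$per_image$Q_std))
  expect_true(all(res$per_image$Q_best >= res$per_image$Q_auto))
  expect_gte(res$multi$R_multi, res$multi$R_single)
  expect_true(all(is.na(res$robust$R_rob)))

  res2 <- case2_experiment(ser)
  expect_equal(nrow(res2$per_image), 4)
  expect_true(all(res2$per_image$Q_std >= 0 & res2$per_image$Q_std <= 1))
  expect_true(all(res2$per_image$n_found_std <= 4))
})
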