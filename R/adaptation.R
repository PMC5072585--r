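#' @title Feedback parameter adaptation
#' @description The feedback loop: exhaustive grid search maximizing the
#'   quality criterion per image (`p_opt`), or the robustness `R` over a
#'   graded series (`p_rob`), plus best-of selection against the feedforward
#'   baseline, the step-size sensitivity sweep, and the two bundled
#'   benchmark experiments.
#' @name adaptation
NULL

#' Parameter grid for exhaustive search
#'
#' The grid is the Cartesian product of the supplied `w`, `t` and `s` value
#' sets. The threshold axis may instead be given as bounds plus a step
#' `delta`, with `t = seq(t_min, t_max, by = delta)`.
#'
#' @param w,s odd positive integers (value sets; defaults `1`).
#' @param t explicit threshold values in `[0, 1]`, or `NULL` to use bounds.
#' @param t_min,t_max,delta threshold bounds and step; requires
#'   `t_min < t_max` and `0 < delta < t_max - t_min`.
#' @return data.frame of class `param_grid` with columns `w, t, s`.
#' @export
param_grid <- function(w = 1L, t = NULL, s = 1L, t_min = NULL, t_max = NULL,
                       delta = NULL) {
  for (x in w) check_odd(x, "w")
  for (x in s) check_odd(x, "s")
  if (is.null(t)) {
    if (is.null(t_min) || is.null(t_max) || is.null(delta))
      stop("supply either 't' or all of 't_min', 't_max', 'delta'",
           call. = FALSE)
    if (t_min >= t_max) stop("t_min must be < t_max", call. = FALSE)
    if (delta <= 0 || delta >= t_max - t_min)
      stop("'delta' must satisfy 0 < delta < t_max - t_min", call. = FALSE)
    t <- round(seq(t_min, t_max, by = delta), 10)
  }
  if (length(t) == 0L || any(t < 0 | t > 1))
    stop("threshold values must lie in [0, 1]", call. = FALSE)
  g <- expand.grid(w = as.integer(w), t = as.numeric(t), s = as.integer(s),
                   KEEP.OUT.ATTRS = FALSE)
  class(g) <- c("param_grid", "data.frame")
  g
}

#' Quality criterion against explicit ground truth
#'
#' Scores a label mask by [quality_Q()]: objects are classified by nearest
#' prototype (prototypes derived from the clean-scene ground truth) and the
#' fuzzy product quality is returned.
#'
#' @param gt a [ground_truth()] the predictions are scored against.
#' @param features feature set used for classification (default all 5).
#' @param classify if `FALSE`, skip the classification term.
#' @return a `seg_criterion` with a `$score(labels)` function returning `Q`.
#' @export
criterion_quality <- function(gt, features = FEATURE_NAMES, classify = TRUE) {
  proto <- if (classify && length(gt$classes) > 0)
    class_prototypes(gt, features) else NULL
  score <- function(labels) {
    cls <- if (!is.null(proto)) {
      rec <- extract_features(labels)
      classify_objects(rec, proto)
    }
    quality_Q(labels, cls, gt)$Q
  }
  structure(list(type = "quality", score = score, gt = gt,
                 prototypes = proto), class = "seg_criterion")
}

#' Quality criterion against abstract (fuzzy) ground truth
#'
#' @param spec a [fuzzy_spec()].
#' @return a `seg_criterion` with a `$score(labels)` function returning
#'   `Q_feat`.
#' @export
criterion_fuzzy <- function(spec) {
  stopifnot(inherits(spec, "fuzzy_spec"))
  score <- function(labels) quality_feat(extract_features(labels), spec)
  structure(list(type = "fuzzy", score = score, spec = spec),
            class = "seg_criterion")
}

# Deterministic argmax over a grid trace: maximal value, ties broken by
# smallest t, then smallest w, then smallest s.
grid_argmax <- function(grid, values) {
  best <- max(values)
  cand <- which(values >= best)  # exact: values[cand] == best
  cand <- cand[values[cand] == best]
  ord <- order(grid$t[cand], grid$w[cand], grid$s[cand])
  cand[ord[1]]
}

#' Per-image parameter adaptation
#'
#' Runs the pipeline at every grid point, scores each result with the
#' criterion, and returns the maximizer `p_opt` (ties: smallest `t`, then
#' `w`, then `s`).
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param method segmentation method; for `"otsu"` the grid's `t` overrides
#'   the data-driven Otsu value (the pipeline stage becomes a plain
#'   threshold at the grid value).
#' @param grid a [param_grid()].
#' @param criterion a `seg_criterion`.
#' @return an `adaptation_result`: list with `p_opt`, `value`, and the full
#'   `trace` (grid with a `value` column).
#' @export
adapt_per_image <- function(image, method, grid, criterion) {
  stopifnot(inherits(grid, "param_grid"), inherits(criterion, "seg_criterion"))
  # under feedback the grid threshold always drives the threshold stage
  eff_method <- if (method == "otsu") "manual_threshold" else method
  values <- vapply(seq_len(nrow(grid)), function(i) {
    labels <- run_pipeline(image, c(grid$w[i], grid$t[i], grid$s[i]),
                           method = eff_method)
    criterion$score(labels)
  }, numeric(1))
  i <- grid_argmax(grid, values)
  trace <- cbind(as.data.frame(grid), value = values)
  structure(list(p_opt = c(w = grid$w[i], t = grid$t[i], s = grid$s[i]),
                 value = values[i], trace = trace, method = method,
                 mode = "per_image", criterion = criterion$type),
            class = "adaptation_result")
}

#' Robust parameter adaptation over a series
#'
#' For each grid point, all images of the series are segmented with that
#' fixed parameter vector, the robustness `R` (mean criterion value) is
#' computed, and the `R`-maximizer `p_rob` is returned (same tie rule as
#' [adapt_per_image()]).
#'
#' @param series a `benchmark_series` (or any list of images in `$images`).
#' @param method,grid,criterion as in [adapt_per_image()].
#' @return an `adaptation_result` with `p_opt = p_rob`, `value = R`, the
#'   grid `trace`, and the per-image quality matrix `Q` (grid x images).
#' @export
adapt_robust <- function(series, method, grid, criterion) {
  stopifnot(inherits(grid, "param_grid"), inherits(criterion, "seg_criterion"))
  images <- series$images
  if (length(images) == 0L) stop("empty series", call. = FALSE)
  eff_method <- if (method == "otsu") "manual_threshold" else method
  Q <- matrix(0, nrow(grid), length(images))
  for (i in seq_len(nrow(grid))) {
    for (j in seq_along(images)) {
      labels <- run_pipeline(images[[j]], c(grid$w[i], grid$t[i], grid$s[i]),
                             method = eff_method)
      Q[i, j] <- criterion$score(labels)
    }
  }
  values <- rowSums(Q) / ncol(Q)
  i <- grid_argmax(grid, values)
  trace <- cbind(as.data.frame(grid), value = values)
  structure(list(p_opt = c(w = grid$w[i], t = grid$t[i], s = grid$s[i]),
                 value = values[i], trace = trace, Q = Q, method = method,
                 mode = "robust", criterion = criterion$type),
            class = "adaptation_result")
}

#' @export
print.adaptation_result <- function(x, ...) {
  cat(sprintf(
    "adaptation_result (%s, %s, criterion %s): p = (w=%d, t=%.4g, s=%d), value = %.4f\n",
    x$mode, x$method, x$criterion, x$p_opt[["w"]], x$p_opt[["t"]],
    x$p_opt[["s"]], x$value))
  cat(sprintf("  grid: %d points\n", nrow(x$trace)))
  invisible(x)
}

#' Best-of selection between feedforward and feedback results
#'
#' Returns the result with the higher criterion value; ties go to the
#' feedback result, so the selection never scores below the feedforward
#' baseline.
#'
#' @param feedforward,feedback lists carrying a `$value` (e.g. an
#'   `adaptation_result`, or `list(value = Q, ...)` for a fixed-parameter
#'   run). Both must be scored with the same criterion on the same image.
#' @return the chosen result, with `$chosen` set to `"feedforward"` or
#'   `"feedback"`.
#' @export
best_of <- function(feedforward, feedback) {
  if (feedback$value >= feedforward$value) {
    feedback$chosen <- "feedback"
    feedback
  } else {
    feedforward$chosen <- "feedforward"
    feedforward
  }
}

# Feedforward (standard) segmentation of one image: Otsu picks its own
# threshold; Sobel uses the mean-gradient heuristic threshold. w and s stay
# at the neutral defaults unless given.
feedforward_result <- function(image, method, criterion,
                               p = c(w = 1, t = 0.5, s = 1)) {
  if (method == "otsu") {
    labels <- run_pipeline(image, p, method = "otsu")
  } else if (method == "sobel_edge") {
    t_std <- std_edge_threshold(mean_filter(image, p[["w"]]))
    p[["t"]] <- t_std
    labels <- run_pipeline(image, p, method = "sobel_edge")
  } else {
    labels <- run_pipeline(image, p, method = method)
  }
  list(value = criterion$score(labels), p = attr(labels, "p"),
       labels = labels, mode = "feedforward", method = method)
}

#' Step-size sensitivity sweep
#'
#' For each grid step `delta`, adapts the threshold per image over the whole
#' series and reports the robustness `R` of the achieved quality values.
#' With aligned endpoints, halving `delta` gives a superset grid, so `R` is
#' non-increasing in `delta`.
#'
#' @param series a `benchmark_series`.
#' @param method segmentation method.
#' @param deltas numeric vector of step sizes.
#' @param t_min,t_max threshold bounds shared by all grids.
#' @param criterion a `seg_criterion`; defaults to explicit quality against
#'   the series ground truth.
#' @return data.frame with columns `delta, R`.
#' @export
delta_sweep <- function(series, method, deltas, t_min, t_max,
                        criterion = criterion_quality(series$gt)) {
  rows <- lapply(deltas, function(d) {
    grid <- param_grid(t_min = t_min, t_max = t_max, delta = d)
    Q <- vapply(series$images, function(img)
      adapt_per_image(img, method, grid, criterion)$value, numeric(1))
    data.frame(delta = d, R = robustness_R(Q))
  })
  do.call(rbind, rows)
}

# Default threshold grids of the two methods (bounds and steps of the
# benchmark experiments).
default_grids <- function() {
  list(otsu = list(t_min = 0.10, t_max = 0.78, delta = 0.02),
       sobel_edge = list(t_min = 0.01, t_max = 0.21, delta = 0.01))
}

#' Explicit-ground-truth benchmark experiment (Case 1)
#'
#' Reproduces the standard-vs-feedback comparison on a graded series:
#' feedforward baselines (StdOtsu, StdEdge), per-image threshold adaptation
#' (AutoOtsu, AutoEdge) with best-of selection, robust threshold adaptation
#' (RobOtsu, RobEdge), and optionally simultaneous (w, t, s) adaptation
#' (MultiAuto) against single-threshold adaptation on the embedded 1-D grid
#' (SingleAuto).
#'
#' @param series a `benchmark_series`.
#' @param methods segmentation methods to compare.
#' @param grids named list of per-method threshold bounds
#   (`t_min`, `t_max`, `delta`).
#' @param robust if `TRUE` (default), also run the robust-mode search
#'   (`p_rob`, `R_rob`) per method.
#' @param multi if `TRUE`, run the multi-parameter comparison.
#' @param multi_w,multi_s value sets of the multi-parameter grid.
#' @param multi_t threshold bounds of the multi-parameter grid.
#' @param features_single,features_multi feature sets for classification in
#'   the single- and multi-parameter settings (5 and 3 features).
#' @return list with `per_image` (long data.frame: `b, n, A, method, Q_std,
#'   Q_auto, Q_best, t_std, t_opt`), `robust` (per-method `R_std, R_auto,
#'   R_best, R_rob, t_rob`), and if `multi` a `multi` block with per-image
#'   qualities and `R_single`, `R_multi`.
#' @export
case1_experiment <- function(series, methods = c("otsu", "sobel_edge"),
                             grids = default_grids(), robust = TRUE,
                             multi = TRUE,
                             multi_w = c(3L, 5L), multi_s = c(3L, 5L, 7L, 9L, 11L),
                             multi_t = list(t_min = 0.01, t_max = 0.99,
                                            delta = 0.04),
                             features_single = FEATURE_NAMES,
                             features_multi = c("area", "eccentricity",
                                                "solidity")) {
  crit5 <- criterion_quality(series$gt, features_single)
  B <- length(series$images)
  per_image <- list()
  rob_rows <- list()
  for (method in methods) {
    g <- grids[[method]]
    grid <- param_grid(t_min = g$t_min, t_max = g$t_max, delta = g$delta)
    rows <- lapply(seq_len(B), function(b) {
      img <- series$images[[b]]
      std <- feedforward_result(img, method, crit5)
      auto <- adapt_per_image(img, method, grid, crit5)
      best <- best_of(std, auto)
      data.frame(b = b, n = series$levels$n[b], A = series$levels$A[b],
                 method = method, Q_std = std$value, Q_auto = auto$value,
                 Q_best = best$value, t_std = std$p[["t"]],
                 t_opt = auto$p_opt[["t"]])
    })
    rows <- do.call(rbind, rows)
    per_image[[method]] <- rows
    rob <- if (robust) adapt_robust(series, method, grid, crit5)
    rob_rows[[method]] <- data.frame(
      method = method, R_std = robustness_R(rows$Q_std),
      R_auto = robustness_R(rows$Q_auto),
      R_best = robustness_R(rows$Q_best),
      R_rob = if (robust) rob$value else NA_real_,
      t_rob = if (robust) rob$p_opt[["t"]] else NA_real_)
  }
  out <- list(per_image = do.call(rbind, per_image),
              robust = do.call(rbind, rob_rows))
  if (!is.null(out$per_image)) rownames(out$per_image) <- NULL
  if (!is.null(out$robust)) rownames(out$robust) <- NULL
  if (multi) {
    crit3 <- criterion_quality(series$gt, features_multi)
    grid3 <- param_grid(w = multi_w, s = multi_s, t_min = multi_t$t_min,
                        t_max = multi_t$t_max, delta = multi_t$delta)
    # 1-D t-grid embedded in the 3-D grid: w and s pinned to the first values
    grid1 <- param_grid(w = multi_w[1], s = multi_s[1],
                        t_min = multi_t$t_min, t_max = multi_t$t_max,
                        delta = multi_t$delta)
    rows <- lapply(seq_len(B), function(b) {
      img <- series$images[[b]]
      single <- adapt_per_image(img, "manual_threshold", grid1, crit3)
      mlt <- adapt_per_image(img, "manual_threshold", grid3, crit3)
      data.frame(b = b, A = series$levels$A[b], Q_single = single$value,
                 Q_multi = mlt$value)
    })
    rows <- do.call(rbind, rows)
    out$multi <- list(per_image = rows,
                      R_single = robustness_R(rows$Q_single),
                      R_multi = robustness_R(rows$Q_multi))
  }
  out
}

#' Abstract-ground-truth benchmark experiment (Case 2)
#'
#' Searches the series for the target objects ("set screws") described only
#' by trapezoidal fuzzy feature ranges and a target count. Feedforward and
#' per-image threshold-adapted segmentation are scored by `Q_feat`; the
#' number of distinct target ground-truth objects retrieved by the fuzzy
#' selection is reported for both.
#'
#' @param series a `benchmark_series`.
#' @param spec a [fuzzy_spec()]; defaults to [setscrew_spec()] of the series
#'   ground truth.
#' @param target_class ground-truth class of the target objects.
#' @param methods segmentation methods.
#' @param grids per-method threshold bounds, as in [case1_experiment()].
#' @return list with `per_image` (`b, A, method, Q_std, Q_auto, n_found_std,
#'   n_found_auto, t_opt`) and `robust` (`method, R_std, R_auto`).
#' @export
case2_experiment <- function(series, spec = setscrew_spec(series$gt,
                                                          target_class),
                             target_class = 1L,
                             methods = c("otsu", "sobel_edge"),
                             grids = default_grids()) {
  crit <- criterion_fuzzy(spec)
  gt_lab <- series$gt$labels
  gt_targets <- which(series$gt$classes == target_class)
  gt_px <- tabulate(gt_lab[gt_lab > 0L], length(series$gt$classes))
  n_found <- function(labels) {
    rec <- extract_features(labels)
    sel <- select_target_objects(rec, spec)
    if (nrow(sel) == 0L) return(0L)
    keep <- matrix(labels %in% sel$id & labels > 0L, nrow(labels))
    m <- match_objects(label_components(keep) , gt_lab)
    # a target counts as retrieved when a selected object covers at least
    # half of it
    hits <- m$gt[m$gt %in% gt_targets & m$overlap >= 0.5 * gt_px[m$gt]]
    length(unique(hits))
  }
  B <- length(series$images)
  per_image <- list()
  for (method in methods) {
    g <- grids[[method]]
    grid <- param_grid(t_min = g$t_min, t_max = g$t_max, delta = g$delta)
    rows <- lapply(seq_len(B), function(b) {
      img <- series$images[[b]]
      std <- feedforward_result(img, method, crit)
      auto <- adapt_per_image(img, method, grid, crit)
      lab_auto <- run_pipeline(
        img, auto$p_opt,
        method = if (method == "otsu") "manual_threshold" else method)
      data.frame(b = b, A = series$levels$A[b], method = method,
                 Q_std = std$value, Q_auto = auto$value,
                 n_found_std = n_found(std$labels),
                 n_found_auto = n_found(lab_auto),
                 t_opt = auto$p_opt[["t"]])
    })
    per_image[[method]] <- do.call(rbind, rows)
  }
  per_image <- do.call(rbind, per_image)
  rownames(per_image) <- NULL
  robust <- do.call(rbind, lapply(methods, function(m) {
    sub <- per_image[per_image$method == m, ]
    data.frame(method = m, R_std = robustness_R(sub$Q_std),
               R_auto = robustness_R(sub$Q_auto))
  }))
  list(per_image = per_image, robust = robust, spec = spec)
}
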