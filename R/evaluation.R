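#' @title Quality criteria
#' @description Explicit-ground-truth quality `Q = mu1 * mu2 * mu3` (object
#'   count, pixel overlap, and pixel classification terms), robustness `R`
#'   (mean `Q` over a graded series), trapezoidal fuzzy membership, and the
#'   abstract-ground-truth criterion `Q_feat`.
#' @name evaluation
NULL

#' Trapezoidal fuzzy membership
#'
#' Membership is 0 below `a` and above `d`, ramps linearly on `(a, b]` and
#' `[c, d)`, and is 1 on the plateau `(b, c]`. Degenerate coincident edges
#' (`a = b` or `c = d`) give step sides, with the plateau value winning at
#' the coincident edge.
#'
#' @param f feature value(s); vectorized.
#' @param a,b,c,d trapezoid edges with `a <= b <= c <= d`.
#' @return membership value(s) in `[0, 1]`.
#' @examples
#' trapezoid_membership(150, 50, 100, 200, 250)  # 1
#' trapezoid_membership(40, 50, 100, 200, 250)   # 0
#' trapezoid_membership(75, 50, 100, 200, 250)   # 0.5
#' @export
trapezoid_membership <- function(f, a, b, c, d) {
  if (!(a <= b && b <= c && c <= d))
    stop("trapezoid edges must satisfy a <= b <= c <= d", call. = FALSE)
  left <- ifelse(f >= b, 1, ifelse(f <= a, 0, (f - a) / (b - a)))
  right <- ifelse(f <= c, 1, ifelse(f >= d, 0, (d - f) / (d - c)))
  pmin(left, right)
}

#' Abstract ground truth as trapezoidal fuzzy ranges
#'
#' @param features named list of length-4 numeric vectors `(a, b, c, d)`,
#'   one per feature column of [extract_features()].
#' @param count optional length-4 edges for the object-count term `theta_c`.
#' @param n_c optional known target object count; when given, `theta_c` is 1
#'   and scoring restricts to the selected top-`n_c` objects.
#' @return a `fuzzy_spec` list.
#' @export
fuzzy_spec <- function(features, count = NULL, n_c = NULL) {
  check_edges <- function(e, nm) {
    if (length(e) != 4 || any(diff(e) < 0))
      stop(sprintf("edges for '%s' must be 4 non-decreasing values", nm),
           call. = FALSE)
  }
  for (nm in names(features)) check_edges(features[[nm]], nm)
  if (!is.null(count)) check_edges(count, "count")
  if (is.null(count) && is.null(n_c))
    stop("provide count edges or a known n_c", call. = FALSE)
  structure(list(features = features, count = count,
                 n_c = if (!is.null(n_c)) as.integer(n_c)),
            class = "fuzzy_spec")
}

#' Greedy one-to-one object matching by pixel overlap
#'
#' Candidate (predicted, ground-truth) pairs are ordered by decreasing pixel
#' overlap (ties by lower predicted then ground-truth id) and matched
#' greedily, each object at most once. Zero-overlap pairs are never matched.
#'
#' @param pred,gt integer label matrices of equal shape.
#' @return data.frame with columns `pred, gt, overlap` (possibly zero rows).
#' @export
match_objects <- function(pred, gt) {
  if (!all(dim(pred) == dim(gt)))
    stop("label masks must have equal shape", call. = FALSE)
  both <- pred > 0L & gt > 0L
  empty <- data.frame(pred = integer(0), gt = integer(0), overlap = integer(0))
  if (!any(both)) return(empty)
  n_gt <- max(gt)
  code <- (pred[both] - 1L) * n_gt + gt[both]
  tab <- tabulate(code, max(code))
  nz <- which(tab > 0L)
  cand <- data.frame(pred = (nz - 1L) %/% n_gt + 1L,
                     gt = (nz - 1L) %% n_gt + 1L,
                     overlap = tab[nz])
  cand <- cand[order(-cand$overlap, cand$pred, cand$gt), , drop = FALSE]
  used_p <- logical(max(cand$pred))
  used_g <- logical(n_gt)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!used_p[cand$pred[i]] && !used_g[cand$gt[i]]) {
      keep[i] <- TRUE
      used_p[cand$pred[i]] <- TRUE
      used_g[cand$gt[i]] <- TRUE
    }
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Segmentation/classification quality against explicit ground truth
#'
#' Three raw measures are fuzzified by `mu_i = clamp(1 - q_i, 0, 1)` and
#' multiplied into `Q = mu1 * mu2 * mu3`:
#' * `q1 = |n_pred - n_gt| / max(n_gt, 1)` -- object-count deviation;
#' * `q2` -- non-overlapping pixels (unmatched ground-truth objects,
#'   unmatched predictions, and the symmetric difference over matched pairs)
#'   over total ground-truth object pixels;
#' * `q3` -- pixels of matched predicted objects whose assigned class differs
#'   from the matched ground-truth object's class, over all matched predicted
#'   pixels (1 when nothing is matched).
#'
#' An empty ground truth scores 1 against an empty prediction and 0
#' otherwise.
#'
#' @param pred integer label matrix of the prediction.
#' @param pred_classes integer class per predicted object (e.g. from
#'   [classify_objects()]); `NULL` skips the classification term (`q3 = 0`).
#' @param gt a [ground_truth()].
#' @return a `quality_report` list with `q1..q3`, `mu1..mu3`, `Q`, counts,
#'   and a diagnostic foreground Jaccard index.
#' @export
quality_Q <- function(pred, pred_classes, gt) {
  stopifnot(inherits(gt, "ground_truth"))
  n_pred <- max(0L, max(pred))
  n_gt <- length(gt$classes)
  if (n_gt == 0L) {
    q <- as.numeric(n_pred > 0)
    return(structure(list(q1 = q, q2 = q, q3 = 0, mu1 = 1 - q, mu2 = 1 - q,
                          mu3 = 1, Q = (1 - q)^2, n_pred = n_pred, n_gt = 0L,
                          n_matched = 0L, jaccard = as.numeric(n_pred == 0)),
                     class = "quality_report"))
  }
  pred_px <- tabulate(pred[pred > 0L], n_pred)
  gt_px <- tabulate(gt$labels[gt$labels > 0L], n_gt)
  total_gt <- sum(gt_px)
  m <- match_objects(pred, gt$labels)
  q1 <- abs(n_pred - n_gt) / n_gt
  unmatched_gt <- sum(gt_px[setdiff(seq_len(n_gt), m$gt)])
  unmatched_pred <- sum(pred_px[setdiff(seq_len(n_pred), m$pred)])
  symdiff <- if (nrow(m)) sum(gt_px[m$gt] + pred_px[m$pred] - 2 * m$overlap)
             else 0
  q2 <- (unmatched_gt + unmatched_pred + symdiff) / total_gt
  if (nrow(m) == 0L) {
    q3 <- 1
  } else if (is.null(pred_classes)) {
    q3 <- 0
  } else {
    wrong <- pred_classes[m$pred] != gt$classes[m$gt]
    q3 <- sum(pred_px[m$pred][wrong]) / sum(pred_px[m$pred])
  }
  mu <- pmin(1, pmax(0, 1 - c(q1, q2, q3)))
  inter <- sum(m$overlap)
  union <- sum(pred_px) + total_gt - inter
  structure(list(q1 = q1, q2 = q2, q3 = q3,
                 mu1 = mu[1], mu2 = mu[2], mu3 = mu[3],
                 Q = mu[1] * mu[2] * mu[3],
                 n_pred = n_pred, n_gt = n_gt, n_matched = nrow(m),
                 jaccard = if (union > 0) inter / union else 1),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf(
    "quality_report: Q = %.4f (mu = %.3f %.3f %.3f; q = %.3f %.3f %.3f)\n",
    x$Q, x$mu1, x$mu2, x$mu3, x$q1, x$q2, x$q3))
  cat(sprintf("  objects: %d predicted / %d ground truth, %d matched; JI = %.3f\n",
              x$n_pred, x$n_gt, x$n_matched, x$jaccard))
  invisible(x)
}

#' Robustness of a quality series
#'
#' The arithmetic mean of the quality values over the graded artifact series.
#'
#' @param Q numeric vector of per-level quality values.
#' @return scalar in `[0, 1]`.
#' @export
robustness_R <- function(Q) {
  if (length(Q) == 0L) stop("empty quality series", call. = FALSE)
  sum(Q) / length(Q)
}

#' Feature-based quality against abstract ground truth
#'
#' `Q_feat = theta_c(n_t) / n_t * sum_i prod_j theta(f_ij)`. When the target
#' count `n_c` is known, `theta_c` is 1 and the sum runs over the selected
#' top-`n_c` objects (still normalized by the total object count `n_t`, so
#' spurious objects are penalized). `n_t = 0` scores 0 by convention.
#'
#' @param records feature data.frame from [extract_features()].
#' @param spec a [fuzzy_spec()].
#' @return scalar in `[0, 1]`.
#' @export
quality_feat <- function(records, spec) {
  stopifnot(inherits(spec, "fuzzy_spec"))
  n_t <- nrow(records)
  if (n_t == 0L) return(0)
  p <- fuzzy_products(records, spec)
  if (!is.null(spec$n_c)) {
    sel <- select_target_objects(records, spec)
    sum(sel$fuzzy_product) / n_t
  } else {
    e <- spec$count
    theta_c <- trapezoid_membership(n_t, e[1], e[2], e[3], e[4])
    theta_c * sum(p) / n_t
  }
}

#' Set-screw style fuzzy spec derived from a clean scene
#'
#' Builds the abstract ground truth for the "find the set screws" experiment:
#' area edges proportional to the mean ground-truth area of the target class
#' (the shape `(0, 5/6, 7/6, 8/6)` of the mean), eccentricity edges
#' `(0.6, 0.85, 0.95, 0.96)`, solidity edges `(0.85, 0.95, 1, 1)`, count
#' edges `(n_c - 2, n_c, n_c, n_c + 2)`, with `n_c` the true target count
#' (known by default).
#'
#' @param gt a [ground_truth()] of the clean scene.
#' @param target_class class index of the target objects (default 1).
#' @param known_n_c if `TRUE` (default) the target count is treated as known.
#' @return a [fuzzy_spec()].
#' @export
setscrew_spec <- function(gt, target_class = 1L, known_n_c = TRUE) {
  stopifnot(inherits(gt, "ground_truth"))
  rec <- extract_features(gt$labels)
  tgt <- which(gt$classes == target_class)
  if (length(tgt) == 0L)
    stop("no ground-truth objects of the target class", call. = FALSE)
  abar <- mean(rec$area[tgt])
  k <- length(tgt)
  fuzzy_spec(
    features = list(
      area = abar / 6000 * c(0, 5000, 7000, 8000),
      eccentricity = c(0.6, 0.85, 0.95, 0.96),
      solidity = c(0.85, 0.95, 1, 1)
    ),
    count = c(max(0, k - 2), k, k, k + 2),
    n_c = if (known_n_c) k
  )
}
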