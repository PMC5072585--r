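#' @title Parameterized segmentation pipeline
#' @description The feedforward pipeline is mean-filter smoothing, a
#'   segmentation stage (global intensity threshold, Otsu threshold, or Sobel
#'   edge detection), morphological opening, and connected-component labeling.
#'   All stages operate on 2-D grayscale matrices with intensities in `[0, 1]`.
#' @name pipeline
NULL

check_image <- function(image) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix", call. = FALSE)
  rng <- range(image)
  if (is.na(rng[1]) || rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop("image intensities must lie in [0, 1]", call. = FALSE)
  image
}

check_odd <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 1 || x != round(x) ||
      x %% 2 == 0)
    stop(sprintf("'%s' must be an odd positive integer, got %s", name,
                 paste(x, collapse = ",")), call. = FALSE)
  as.integer(x)
}

# Replicate (edge) padding by r pixels on every side.
pad_replicate <- function(image, r) {
  nr <- nrow(image); nc <- ncol(image)
  ri <- c(rep(1L, r), seq_len(nr), rep(nr, r))
  ci <- c(rep(1L, r), seq_len(nc), rep(nc, r))
  image[ri, ci, drop = FALSE]
}

# Shifted view of a 1-padded image: offset (di, dj) in row/col direction.
shift1 <- function(padded, di, dj, nr, nc) {
  padded[(2L + di):(nr + 1L + di), (2L + dj):(nc + 1L + dj), drop = FALSE]
}

#' Mean (box) filter
#'
#' Smooths an image with a symmetric `w` x `w` convolution kernel whose
#' elements all equal `1/w^2`, using replicate padding at the border.
#' Implemented with a summed-area table, so cost is independent of `w`.
#'
#' @param image numeric matrix with values in `[0, 1]`.
#' @param w odd positive integer, kernel side length. `w = 1` is the identity.
#' @return matrix of the same dimensions; values stay within the input range.
#' @examples
#' img <- matrix(0, 3, 3); img[2, 2] <- 0.9
#' mean_filter(img, 3)[2, 2]  # 0.1
#' @export
mean_filter <- function(image, w) {
  check_image(image)
  w <- check_odd(w, "w")
  if (w == 1L) return(image)
  r <- w %/% 2L
  p <- pad_replicate(image, r)
  # integral image with a zero first row/column
  s <- rbind(0, apply(p, 2, cumsum))
  s <- cbind(0, t(apply(s, 1, cumsum)))
  nr <- nrow(image); nc <- ncol(image)
  i1 <- seq_len(nr); j1 <- seq_len(nc)
  (s[i1 + w, j1 + w, drop = FALSE] - s[i1, j1 + w, drop = FALSE] -
      s[i1 + w, j1, drop = FALSE] + s[i1, j1, drop = FALSE]) / (w * w)
}

#' Global intensity thresholding
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param t threshold in `[0, 1]`. Pixels strictly greater than `t` are
#'   foreground; `t = 1` therefore always yields an empty mask.
#' @return logical matrix.
#' @export
threshold_segment <- function(image, t) {
  check_image(image)
  stopifnot_scalar(t, "t")
  if (t < 0 || t > 1) stop("'t' must lie in [0, 1]", call. = FALSE)
  image > t
}

#' Otsu threshold
#'
#' Global gray-level threshold minimizing the within-class intensity variance
#' (equivalently, maximizing the between-class variance) over a 256-bin
#' histogram of the image. The returned value feeds [threshold_segment()].
#'
#' @param image numeric matrix in `[0, 1]` with at least two distinct values.
#' @param nbins number of histogram bins (default 256).
#' @return threshold in `[0, 1]`, placed at a bin boundary `k/nbins`.
#' @export
otsu_threshold <- function(image, nbins = 256L) {
  check_image(image)
  rng <- range(image)
  if (rng[1] == rng[2])
    stop("otsu_threshold: image is constant (degenerate input)", call. = FALSE)
  bin <- pmin(floor(image * nbins) + 1L, nbins)
  counts <- tabulate(bin, nbins)
  p <- counts / sum(counts)
  centers <- (seq_len(nbins) - 0.5) / nbins
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[nbins]
  # between-class variance for split after bin k (k = 1..nbins-1)
  k <- seq_len(nbins - 1L)
  w0k <- w0[k]
  valid <- w0k > 0 & w0k < 1
  sb <- rep(-Inf, nbins - 1L)
  sb[valid] <- (mu_t * w0k[valid] - mu[k][valid])^2 /
    (w0k[valid] * (1 - w0k[valid]))
  best <- which.max(sb)
  best / nbins
}

# Sobel gradient magnitude with replicate padding. Kernels carry the 1/8
# per-axis normalization of MATLAB's fspecial('sobel')-based edge(): a unit
# step edge yields magnitude 1/2. Published t_edge ranges assume this scale.
sobel_magnitude <- function(image) {
  check_image(image)
  nr <- nrow(image); nc <- ncol(image)
  p <- pad_replicate(image, 1L)
  s <- function(di, dj) shift1(p, di, dj, nr, nc)
  gx <- (s(-1, 1) + 2 * s(0, 1) + s(1, 1) -
           s(-1, -1) - 2 * s(0, -1) - s(1, -1)) / 8
  gy <- (s(1, -1) + 2 * s(1, 0) + s(1, 1) -
           s(-1, -1) - 2 * s(-1, 0) - s(-1, 1)) / 8
  sqrt(gx^2 + gy^2)
}

#' Sobel edge segmentation
#'
#' Computes the Sobel gradient magnitude, thresholds it at `t_edge`, dilates
#' the edge mask with a 3 x 3 square so contours close, and fills enclosed
#' holes so closed contours become solid blobs.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param t_edge gradient-magnitude threshold in `[0, 1]` (strict `>`).
#' @param fill if `TRUE` (default) fill enclosed holes after dilation.
#' @return logical matrix.
#' @export
sobel_segment <- function(image, t_edge, fill = TRUE) {
  stopifnot_scalar(t_edge, "t_edge")
  if (t_edge < 0 || t_edge > 1)
    stop("'t_edge' must lie in [0, 1]", call. = FALSE)
  mask <- sobel_magnitude(image) > t_edge
  se <- square_se(3L)
  mask <- .binary_morph(mask, se$dr, se$dc, FALSE)
  if (fill) mask <- .fill_holes(mask)
  mask
}

# Default threshold of the feedforward Sobel method, following MATLAB's
# edge(): the squared magnitude is cut at scale * its mean, i.e. the
# magnitude threshold is sqrt(scale * mean(mag^2)).
std_edge_threshold <- function(image, scale = 4) {
  mag <- sobel_magnitude(image)
  min(1, sqrt(scale * mean(mag^2)))
}

# Structuring elements as row/col offset lists.
disk_se <- function(s) {
  s <- check_odd(s, "s")
  r <- s %/% 2L
  off <- expand.grid(dr = -r:r, dc = -r:r)
  keep <- off$dr^2 + off$dc^2 <= r^2
  list(dr = as.integer(off$dr[keep]), dc = as.integer(off$dc[keep]))
}

square_se <- function(s) {
  r <- s %/% 2L
  off <- expand.grid(dr = -r:r, dc = -r:r)
  list(dr = as.integer(off$dr), dc = as.integer(off$dc))
}

#' Binary erosion and dilation
#'
#' @param mask logical matrix.
#' @param se structuring element from `disk_se()`/`square_se()` (offset list).
#' @return logical matrix.
#' @keywords internal
#' @noRd
erode <- function(mask, se) .binary_morph(mask, se$dr, se$dc, TRUE)
dilate <- function(mask, se) .binary_morph(mask, se$dr, se$dc, FALSE)

#' Morphological opening with a disk
#'
#' Erosion followed by dilation with a disk-shaped structuring element of
#' diameter `s` pixels (radius `floor(s/2)`). Removes foreground structures
#' smaller than the disk; anti-extensive and idempotent. `s = 1` is the
#' identity.
#'
#' @param mask logical matrix.
#' @param s odd positive integer, disk diameter.
#' @return logical matrix, a subset of `mask`.
#' @export
opening <- function(mask, s) {
  if (!is.logical(mask) || !is.matrix(mask))
    stop("mask must be a logical matrix", call. = FALSE)
  s <- check_odd(s, "s")
  if (s == 1L) return(mask)
  se <- disk_se(s)
  dilate(erode(mask, se), se)
}

#' Connected-component labeling
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return integer matrix with 0 background and labels `1..n` assigned in
#'   deterministic scan order.
#' @export
label_components <- function(mask, connectivity = 8L) {
  if (!is.logical(mask) || !is.matrix(mask))
    stop("mask must be a logical matrix", call. = FALSE)
  .cc_label(mask, as.integer(connectivity))
}

#' Fill enclosed holes in a binary mask
#'
#' Background regions not connected (4-connectivity) to the image border are
#' turned into foreground.
#'
#' @param mask logical matrix.
#' @return logical matrix.
#' @export
fill_holes <- function(mask) {
  if (!is.logical(mask) || !is.matrix(mask))
    stop("mask must be a logical matrix", call. = FALSE)
  .fill_holes(mask)
}

#' Run the full segmentation pipeline
#'
#' Applies `mean_filter(w)`, the chosen segmentation stage, `opening(s)`, and
#' connected-component labeling, in that order.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param p parameter vector: named or positional numeric `c(w, t, s)` with
#'   `w`, `s` odd positive integers and `t` in `[0, 1]`.
#' @param method one of `"manual_threshold"`, `"otsu"`, `"sobel_edge"`. For
#'   `"otsu"` the `t` component of `p` is ignored and replaced by
#'   [otsu_threshold()] of the smoothed image.
#' @param connectivity labeling connectivity, 4 or 8.
#' @return integer label matrix (0 = background, labels `1..n_t`); the
#'   effective parameter vector is attached as attribute `"p"`.
#' @examples
#' scene <- render_scene(default_scene(size = 64))
#' lab <- run_pipeline(scene$image, c(w = 1, t = 0.5, s = 1),
#'                     method = "manual_threshold")
#' max(lab)  # number of segmented objects
#' @export
run_pipeline <- function(image, p,
                         method = c("manual_threshold", "otsu", "sobel_edge"),
                         connectivity = 8L) {
  method <- match.arg(method)
  p <- as_param_vector(p)
  img <- mean_filter(image, p[["w"]])
  t_eff <- p[["t"]]
  mask <- switch(method,
    manual_threshold = threshold_segment(img, t_eff),
    otsu = {
      t_eff <- otsu_threshold(img)
      threshold_segment(img, t_eff)
    },
    sobel_edge = sobel_segment(img, t_eff)
  )
  mask <- opening(mask, p[["s"]])
  labels <- label_components(mask, connectivity)
  attr(labels, "p") <- c(w = p[["w"]], t = t_eff, s = p[["s"]])
  labels
}

#' Coerce to a parameter vector (w, t, s)
#'
#' @param p numeric length-3 vector, named or in (w, t, s) order, or a list.
#' @return named numeric vector `c(w, t, s)` after validation.
#' @export
as_param_vector <- function(p) {
  p <- unlist(p)
  if (length(p) != 3L)
    stop("parameter vector must have 3 components (w, t, s)", call. = FALSE)
  if (is.null(names(p)) || !all(c("w", "t", "s") %in% names(p)))
    names(p) <- c("w", "t", "s")
  p <- p[c("w", "t", "s")]
  check_odd(p[["w"]], "w")
  check_odd(p[["s"]], "s")
  if (p[["t"]] < 0 || p[["t"]] > 1)
    stop("'t' must lie in [0, 1]", call. = FALSE)
  p
}
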