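#' @title Synthetic graded-artifact benchmark
#' @description Generates scenes of solid objects of several classes with full
#'   pixel ground truth, then degrades them with `B` shading levels
#'   (multiplicative planar ramp) and `N` Gaussian-noise levels, summarized by
#'   a scalar artifact level `A` in `[0, 1]`.
#' @name synthetic_benchmark
NULL

#' Describe one scene object
#'
#' @param shape `"disk"`, `"rectangle"` or `"capsule"`.
#' @param class integer object class in `1..K`.
#' @param center numeric `(row, col)` center in pixels.
#' @param size shape size in pixels: disk radius; rectangle `c(height, width)`;
#'   capsule `c(length, width)` (total length including the round caps).
#' @param intensity gray value in `[0, 1]`.
#' @param angle orientation in degrees, used by capsules (0 = horizontal).
#' @return a `scene_object` list.
#' @export
scene_object <- function(shape = c("disk", "rectangle", "capsule"),
                         class, center, size, intensity, angle = 0) {
  shape <- match.arg(shape)
  if (intensity < 0 || intensity > 1)
    stop("object intensity must lie in [0, 1]", call. = FALSE)
  if (class < 1 || class != round(class))
    stop("object class must be a positive integer", call. = FALSE)
  structure(list(shape = shape, class = as.integer(class),
                 center = as.numeric(center), size = as.numeric(size),
                 intensity = intensity, angle = angle),
            class = "scene_object")
}

#' Specify a synthetic scene
#'
#' @param objects list of [scene_object()]s. Objects must lie fully inside the
#'   frame and must not overlap; every class `1..K` must appear at least once.
#' @param width,height frame size in pixels.
#' @param background background gray value in `[0, 1]`.
#' @param scene_id integer scene index `r` (provenance only).
#' @param seed master seed for all degradations derived from this scene.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(objects, width = 128L, height = 128L,
                       background = 0.15, scene_id = 1L, seed = 1L) {
  if (background < 0 || background > 1)
    stop("background must lie in [0, 1]", call. = FALSE)
  if (length(objects) > 0) {
    classes <- vapply(objects, `[[`, integer(1), "class")
    k_max <- max(classes)
    if (!all(seq_len(k_max) %in% classes))
      stop("every object class 1..K must appear at least once", call. = FALSE)
  }
  structure(list(objects = objects, width = as.integer(width),
                 height = as.integer(height), background = background,
                 scene_id = as.integer(scene_id), seed = as.integer(seed)),
            class = "scene_spec")
}

# Rasterize one object to a logical mask on the scene frame. Pixel centers
# are at integer coordinates (row, col).
rasterize_object <- function(obj, height, width) {
  rr <- matrix(seq_len(height), height, width)
  cc <- matrix(seq_len(width), height, width, byrow = TRUE)
  r0 <- obj$center[1]; c0 <- obj$center[2]
  mask <- switch(obj$shape,
    disk = (rr - r0)^2 + (cc - c0)^2 <= obj$size[1]^2,
    rectangle = {
      hh <- (obj$size[1] - 1) / 2; hw <- (obj$size[2] - 1) / 2
      abs(rr - r0) <= hh & abs(cc - c0) <= hw
    },
    capsule = {
      len <- obj$size[1]; wid <- obj$size[2]
      if (len < wid) stop("capsule length must be >= width", call. = FALSE)
      th <- obj$angle * pi / 180
      ux <- cos(th); uy <- sin(th)       # unit axis in (col, row) terms
      half <- (len - wid) / 2            # half-length of the core segment
      # distance from each pixel center to the core segment
      dx <- cc - c0; dy <- rr - r0
      proj <- pmin(pmax(dx * ux + dy * uy, -half), half)
      px <- dx - proj * ux; py <- dy - proj * uy
      px^2 + py^2 <= ((wid - 1) / 2)^2
    }
  )
  # "fully inside the frame": no object pixel on the frame border
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0)
    stop("object rasterizes to zero pixels", call. = FALSE)
  if (any(idx[, 1] <= 1 | idx[, 1] >= height | idx[, 2] <= 1 | idx[, 2] >= width))
    stop("object extends to or beyond the frame border", call. = FALSE)
  mask
}

#' Construct a ground-truth object
#'
#' @param labels integer matrix: 0 background, consecutive object ids `1..n`.
#' @param classes integer vector mapping object id to class `1..K`.
#' @return a `ground_truth` list.
#' @export
ground_truth <- function(labels, classes) {
  if (!is.matrix(labels)) stop("labels must be a matrix", call. = FALSE)
  storage.mode(labels) <- "integer"
  n <- max(0L, max(labels))
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) && !identical(ids, seq_len(n)))
    stop("labels must be consecutive positive integers", call. = FALSE)
  classes <- as.integer(classes)
  if (length(classes) != n)
    stop("need one class per labeled object", call. = FALSE)
  if (n > 0 && any(classes < 1L))
    stop("classes must be >= 1", call. = FALSE)
  structure(list(labels = labels, classes = classes), class = "ground_truth")
}

#' Render a scene to a clean image plus ground truth
#'
#' @param spec a [scene_spec()].
#' @return list with `image` (matrix in `[0, 1]`) and `gt` ([ground_truth()]).
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$height; w <- spec$width
  img <- matrix(spec$background, h, w)
  labels <- matrix(0L, h, w)
  for (i in seq_along(spec$objects)) {
    m <- rasterize_object(spec$objects[[i]], h, w)
    if (any(labels[m] > 0L))
      stop(sprintf("object %d overlaps an earlier object", i), call. = FALSE)
    labels[m] <- i
    img[m] <- spec$objects[[i]]$intensity
  }
  classes <- vapply(spec$objects, `[[`, integer(1), "class")
  list(image = img, gt = ground_truth(labels, classes))
}

#' Degrade an image with graded shading and Gaussian noise
#'
#' Shading multiplies the image by a planar ramp that darkens toward the
#' bottom-right corner, with amplitude `shading_max * (b - 1) / (B - 1)`.
#' Noise is additive zero-mean Gaussian with standard deviation
#' `sigma_max * (n - 1) / (N - 1)`. The result is clipped to `[0, 1]`.
#' `(b, n) = (1, 1)` returns the input unchanged.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param b shading level in `1..B`.
#' @param n noise level in `1..N`.
#' @param B,N number of shading / noise levels (defaults 13 and 14).
#' @param seed master seed; the `(b, n)` substream is derived from it, so
#'   adding levels never perturbs existing ones.
#' @param shading_max maximal relative darkening at the far corner (default
#'   0.6).
#' @param sigma_max noise standard deviation at `n = N` (default 0.25).
#' @return degraded matrix in `[0, 1]`, deterministic given `seed`.
#' @export
apply_artifacts <- function(image, b, n, B = 13L, N = 14L, seed = 1L,
                            shading_max = 0.6, sigma_max = 0.25) {
  check_image(image)
  if (b < 1 || b > B) stop("'b' out of range 1..B", call. = FALSE)
  if (n < 1 || n > N) stop("'n' out of range 1..N", call. = FALSE)
  out <- image
  amp <- if (B > 1) shading_max * (b - 1) / (B - 1) else 0
  if (amp > 0) {
    h <- nrow(image); w <- ncol(image)
    ramp <- (matrix(seq_len(h) - 1, h, w) +
               matrix(seq_len(w) - 1, h, w, byrow = TRUE)) / (h - 1 + w - 1)
    out <- out * (1 - amp * ramp)
  }
  sigma <- if (N > 1) sigma_max * (n - 1) / (N - 1) else 0
  if (sigma > 0) {
    noise <- with_seed(derive_seed(seed, b, n),
                       matrix(rnorm(length(out), 0, sigma),
                              nrow(out), ncol(out)))
    out <- out + noise
  }
  pmin(pmax(out, 0), 1)
}

#' Scalar artifact level of a degraded image
#'
#' `A = min(1, RMS(clean - degraded) / norm)`, where `norm` calibrates the
#' maximal degradation `(b, n) = (B, N)` of the scene to `A = 1`.
#'
#' @param clean,degraded matrices of equal dimensions.
#' @param norm positive calibration constant (see [calibrate_artifact_norm()]).
#' @return artifact level in `[0, 1]`.
#' @export
artifact_level <- function(clean, degraded, norm) {
  if (!all(dim(clean) == dim(degraded)))
    stop("clean and degraded images must have equal dimensions", call. = FALSE)
  stopifnot_scalar(norm, "norm")
  min(1, sqrt(mean((clean - degraded)^2)) / norm)
}

#' Calibration constant for the artifact level
#'
#' RMS deviation of the maximally degraded image `(b, n) = (B, N)` from the
#' clean image, under the scene's master seed.
#'
#' @inheritParams apply_artifacts
#' @return positive scalar.
#' @export
calibrate_artifact_norm <- function(image, B = 13L, N = 14L, seed = 1L,
                                    shading_max = 0.6, sigma_max = 0.25) {
  worst <- apply_artifacts(image, B, N, B = B, N = N, seed = seed,
                           shading_max = shading_max, sigma_max = sigma_max)
  sqrt(mean((image - worst)^2))
}

#' Generate a graded benchmark series
#'
#' Renders the scene and produces the diagonal series `A(r, b, b + 1)` for
#' `b = 1..B`: each successive image has one more step of both shading and
#' noise, so artifact levels increase strictly.
#'
#' @param spec a [scene_spec()].
#' @param B,N number of shading / noise levels; requires `B <= N - 1`.
#' @param seed master seed (defaults to the spec's).
#' @param shading_max,sigma_max see [apply_artifacts()].
#' @return a `benchmark_series`: list with `clean`, `gt`, `images` (length
#'   `B`), `levels` (data.frame `scene, b, n, A`), `norm`, the generation
#'   parameters, and the spec.
#' @examples
#' ser <- generate_series(default_scene(size = 64), B = 3)
#' ser$levels
#' @export
generate_series <- function(spec, B = 13L, N = 14L, seed = NULL,
                            shading_max = 0.6, sigma_max = 0.25) {
  stopifnot(inherits(spec, "scene_spec"))
  if (B > N - 1) stop("requires B <= N - 1", call. = FALSE)
  seed <- as.integer(seed %||% spec$seed)
  sc <- render_scene(spec)
  norm <- calibrate_artifact_norm(sc$image, B = B, N = N, seed = seed,
                                  shading_max = shading_max,
                                  sigma_max = sigma_max)
  images <- vector("list", B)
  A <- numeric(B)
  for (b in seq_len(B)) {
    images[[b]] <- apply_artifacts(sc$image, b, b + 1L, B = B, N = N,
                                   seed = seed, shading_max = shading_max,
                                   sigma_max = sigma_max)
    A[b] <- artifact_level(sc$image, images[[b]], norm)
  }
  if (B > 1 && any(diff(A) <= 0))
    stop("artifact levels are not strictly increasing along the series",
         call. = FALSE)
  structure(list(spec = spec, clean = sc$image, gt = sc$gt, images = images,
                 levels = data.frame(scene = spec$scene_id, b = seq_len(B),
                                     n = seq_len(B) + 1L, A = A),
                 norm = norm, B = as.integer(B), N = as.integer(N),
                 seed = seed, shading_max = shading_max,
                 sigma_max = sigma_max),
            class = "benchmark_series")
}

#' @export
print.benchmark_series <- function(x, ...) {
  cat(sprintf(
    "benchmark_series: scene %d, %dx%d px, %d objects, B=%d (N=%d), seed %d\n",
    x$spec$scene_id, x$spec$height, x$spec$width, length(x$spec$objects),
    x$B, x$N, x$seed))
  cat(sprintf("artifact levels A: %s\n",
              paste(sprintf("%.3f", x$levels$A), collapse = " ")))
  invisible(x)
}

#' Default benchmark scene
#'
#' A scene of solid objects on a dark background: four elongated capsules
#' ("set-screw"-like: high eccentricity, solidity 1) of class 1, two disks of
#' class 2, and two squares of class 3. Object widths are large relative to
#' the 2-pixel rim that edge-based segmentation adds around objects, matching
#' the scale ratio of photographic benchmarks; the layout scales with `size`.
#'
#' @param size frame side length in pixels (default 192, minimum 96).
#' @param scene_id,seed passed to [scene_spec()].
#' @param background background intensity.
#' @return a [scene_spec()].
#' @export
default_scene <- function(size = 192L, scene_id = 1L, seed = 1L,
                          background = 0.15) {
  if (size < 96) stop("size must be >= 96", call. = FALSE)
  u <- size / 128  # layout scale factor (coordinates on a 128-px base grid)
  pos <- function(r, c) c(r, c) * u
  odd <- function(x) 2 * round((x * u - 1) / 2) + 1
  cap <- function(r, c, angle)
    scene_object("capsule", class = 1L, center = pos(r, c),
                 size = c(round(39 * u), round(17 * u)), intensity = 0.85,
                 angle = angle)
  objects <- list(
    cap(18, 30, 0), cap(24, 94, 45), cap(105, 20, 90), cap(100, 100, 130),
    scene_object("disk", class = 2L, center = pos(60, 52),
                 size = round(10 * u), intensity = 0.80),
    scene_object("disk", class = 2L, center = pos(86, 60),
                 size = round(9 * u), intensity = 0.80),
    scene_object("rectangle", class = 3L, center = pos(60, 108),
                 size = c(odd(15), odd(15)), intensity = 0.75),
    scene_object("rectangle", class = 3L, center = pos(40, 64),
                 size = c(odd(13), odd(13)), intensity = 0.75)
  )
  scene_spec(objects, width = as.integer(size), height = as.integer(size),
             background = background, scene_id = scene_id, seed = seed)
}

#' Two-level calibration scene
#'
#' A minimal scene with objects at one intensity on a uniform background,
#' used for parameter-recovery checks: any threshold strictly between the two
#' levels segments it perfectly.
#'
#' @param size frame side length.
#' @param object_intensity,background the two gray levels.
#' @param seed master seed.
#' @return a [scene_spec()].
#' @export
two_level_scene <- function(size = 64L, object_intensity = 0.8,
                            background = 0.2, seed = 1L) {
  objects <- list(
    scene_object("disk", class = 1L, center = c(size * 0.3, size * 0.3),
                 size = round(size * 0.09), intensity = object_intensity),
    scene_object("rectangle", class = 1L, center = c(size * 0.7, size * 0.65),
                 size = c(11, 11), intensity = object_intensity)
  )
  scene_spec(objects, width = size, height = size, background = background,
             scene_id = 99L, seed = seed)
}
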