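#' @title Per-object feature extraction and classification
#' @description Geometric region features (area, eccentricity, solidity,
#'   extent, minor axis length) computed from a label mask, nearest-prototype
#'   classification against ground-truth class means, and fuzzy selection of
#'   target objects.
#' @name features
NULL

FEATURE_NAMES <- c("area", "eccentricity", "solidity", "extent",
                   "minor_axis_length")

gcd2 <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

# Number of pixel centers inside the convex hull of a pixel set, via Pick's
# theorem (hull vertices are lattice points, so the count is exact):
#   #lattice = area + boundary/2 + 1.
# Pixel coordinates are distinct by construction.
convex_pixel_count <- function(r, c) {
  n <- length(r)
  if (n <= 2L) return(n)
  h <- grDevices::chull(c, r)
  hx <- c[h]; hy <- r[h]
  m <- length(h)
  if (m <= 2L) {  # collinear set: lattice points on the extreme segment
    dr <- abs(hy[1] - hy[2]); dc <- abs(hx[1] - hx[2])
    return(gcd2(dr, dc) + 1L)
  }
  nx <- c(hx[-1], hx[1]); ny <- c(hy[-1], hy[1])
  area <- abs(sum(hx * ny - nx * hy)) / 2
  edr <- abs(ny - hy); edc <- abs(nx - hx)
  boundary <- sum(vapply(seq_len(m), function(i) gcd2(edr[i], edc[i]),
                         numeric(1)))
  area + boundary / 2 + 1
}

#' Extract per-object features from a label mask
#'
#' Features follow the standard region-properties conventions: `area` is the
#' pixel count; `eccentricity` and `minor_axis_length` come from the ellipse
#' with the same normalized second central moments as the region (with the
#' 1/12 pixel-extent correction); `solidity` is area over convex-image area;
#' `extent` is area over bounding-box area.
#'
#' @param labels integer matrix with 0 background and consecutive labels
#'   `1..n_t`.
#' @return data.frame with columns `id, area, eccentricity, solidity, extent,
#'   minor_axis_length`, one row per object (zero rows for an empty mask).
#' @examples
#' m <- matrix(0L, 8, 8); m[2:5, 2:5] <- 1L
#' extract_features(m)  # area 16, extent 1, solidity 1
#' @export
extract_features <- function(labels) {
  if (!is.matrix(labels)) stop("labels must be a matrix", call. = FALSE)
  idx <- which(labels > 0L)
  empty <- data.frame(id = integer(0), area = numeric(0),
                      eccentricity = numeric(0), solidity = numeric(0),
                      extent = numeric(0), minor_axis_length = numeric(0))
  if (length(idx) == 0L) return(empty)
  lab <- labels[idx]
  n_t <- max(lab)
  if (length(unique(lab)) != n_t)
    stop("labels must be consecutive from 1", call. = FALSE)
  nr <- nrow(labels)
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  # vectorized raw moments per object
  a <- tabulate(lab, n_t)
  sr <- rowsum(rr, lab)[, 1]; sc <- rowsum(cc, lab)[, 1]
  sr2 <- rowsum(rr * rr, lab)[, 1]; sc2 <- rowsum(cc * cc, lab)[, 1]
  src <- rowsum(rr * cc, lab)[, 1]
  mr <- sr / a; mc <- sc / a
  urr <- sr2 / a - mr^2 + 1 / 12
  ucc <- sc2 / a - mc^2 + 1 / 12
  urc <- src / a - mr * mc
  common <- sqrt((urr - ucc)^2 + 4 * urc^2)
  major <- 2 * sqrt(2) * sqrt(urr + ucc + common)
  minor <- 2 * sqrt(2) * sqrt(pmax(urr + ucc - common, 0))
  ecc <- ifelse(major > 0, sqrt(pmax(0, 1 - (minor / major)^2)), 0)
  rs <- split(rr, lab); cs <- split(cc, lab)
  rmin <- vapply(rs, min, numeric(1)); rmax <- vapply(rs, max, numeric(1))
  cmin <- vapply(cs, min, numeric(1)); cmax <- vapply(cs, max, numeric(1))
  extent <- a / ((rmax - rmin + 1) * (cmax - cmin + 1))
  solidity <- vapply(seq_len(n_t), function(i)
    min(1, a[i] / convex_pixel_count(rs[[i]], cs[[i]])), numeric(1))
  data.frame(id = seq_len(n_t), area = a, eccentricity = ecc,
             solidity = solidity, extent = extent,
             minor_axis_length = minor, row.names = NULL)
}

#' Class prototypes from ground truth
#'
#' Mean feature vector per class, computed on the ground-truth objects of the
#' clean scene, together with the z-normalization statistics (per-feature mean
#' and standard deviation over all ground-truth objects) used to scale
#' distances in [classify_objects()].
#'
#' @param gt a [ground_truth()].
#' @param features character vector of feature columns to use (default all 5;
#'   use `c("area", "eccentricity", "solidity")` for the 3-feature setting).
#' @return list with `centers` (K x m matrix), `mean`, `sd`, `features`.
#' @export
class_prototypes <- function(gt, features = FEATURE_NAMES) {
  stopifnot(inherits(gt, "ground_truth"))
  if (length(gt$classes) < 1L)
    stop("ground truth has no objects to derive prototypes from",
         call. = FALSE)
  rec <- extract_features(gt$labels)
  f <- as.matrix(rec[, features, drop = FALSE])
  mu <- colMeans(f)
  sdev <- apply(f, 2, sd)
  sdev[!is.finite(sdev) | sdev < 1e-12] <- 1
  K <- max(gt$classes)
  z <- sweep(sweep(f, 2, mu), 2, sdev, "/")
  centers <- do.call(rbind, lapply(seq_len(K), function(k) {
    colMeans(z[gt$classes == k, , drop = FALSE])
  }))
  rownames(centers) <- seq_len(K)
  list(centers = centers, mean = mu, sd = sdev, features = features)
}

#' Nearest-prototype object classification
#'
#' Each object is assigned to the class whose prototype is nearest in
#' z-normalized Euclidean distance; ties go to the lower class index.
#'
#' @param records feature data.frame from [extract_features()].
#' @param prototypes from [class_prototypes()].
#' @return integer vector of class assignments, one per record.
#' @export
classify_objects <- function(records, prototypes) {
  if (nrow(records) == 0L) return(integer(0))
  if (is.null(prototypes$centers) || nrow(prototypes$centers) < 1L)
    stop("need at least one prototype class", call. = FALSE)
  f <- as.matrix(records[, prototypes$features, drop = FALSE])
  z <- sweep(sweep(f, 2, prototypes$mean), 2, prototypes$sd, "/")
  d2 <- outer(rowSums(z^2), rowSums(prototypes$centers^2), "+") -
    2 * z %*% t(prototypes$centers)
  unname(apply(d2, 1, which.min))
}

# Product over the spec's feature trapezoids for each record.
fuzzy_products <- function(records, spec) {
  if (nrow(records) == 0L) return(numeric(0))
  prod <- rep(1, nrow(records))
  for (nm in names(spec$features)) {
    if (!nm %in% names(records))
      stop(sprintf("fuzzy spec names unknown feature '%s'", nm), call. = FALSE)
    e <- spec$features[[nm]]
    prod <- prod * trapezoid_membership(records[[nm]], e[1], e[2], e[3], e[4])
  }
  prod
}

#' Select target objects under an abstract ground truth
#'
#' Objects are ranked by their fuzzy feature product `prod_j theta(f_ij)`.
#' Zero-product objects are never selected. If the target count `n_c` is
#' known, the top `n_c` are retained (ties by larger area, then lower id);
#' otherwise all objects with positive product are retained.
#'
#' @param records feature data.frame from [extract_features()].
#' @param spec a [fuzzy_spec()].
#' @param n_c target object count; defaults to the spec's (may be `NULL`).
#' @return the selected subset of `records`, with a `fuzzy_product` column.
#' @export
select_target_objects <- function(records, spec, n_c = spec$n_c) {
  p <- fuzzy_products(records, spec)
  records$fuzzy_product <- p
  keep <- records[p > 0, , drop = FALSE]
  if (!is.null(n_c) && nrow(keep) > n_c) {
    ord <- order(-keep$fuzzy_product, -keep$area, keep$id)
    keep <- keep[ord[seq_len(n_c)], , drop = FALSE]
  }
  keep
}
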