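# Independent brute-force oracles, deliberately naive: direct loops and set
# arithmetic, sharing no code with the package internals.

naive_mean_filter <- function(image, w) {
  r <- w %/% 2
  nr <- nrow(image); nc <- ncol(image)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r) {
      ii <- min(max(i + di, 1), nr)
      jj <- min(max(j + dj, 1), nc)
      acc <- acc + image[ii, jj]
    }
    out[i, j] <- acc / (w * w)
  }
  out
}

# exhaustive 256-candidate within-class-variance minimizer
naive_otsu <- function(image, nbins = 256) {
  bin <- pmin(floor(image * nbins) + 1, nbins)
  counts <- tabulate(bin, nbins)
  centers <- (seq_len(nbins) - 0.5) / nbins
  best_k <- NA; best_v <- Inf
  for (k in 1:(nbins - 1)) {
    lo <- counts[1:k]; hi <- counts[(k + 1):nbins]
    if (sum(lo) == 0 || sum(hi) == 0) next
    clo <- centers[1:k]; chi <- centers[(k + 1):nbins]
    mlo <- sum(lo * clo) / sum(lo); mhi <- sum(hi * chi) / sum(hi)
    v <- sum(lo * (clo - mlo)^2) + sum(hi * (chi - mhi)^2)
    if (v < best_v) { best_v <- v; best_k <- k }
  }
  best_k / nbins
}

naive_morph <- function(mask, offsets, erode) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- logical(0)
    for (k in seq_along(offsets$dr)) {
      ii <- i + offsets$dr[k]; jj <- j + offsets$dc[k]
      vals <- c(vals, if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc)
        mask[ii, jj] else FALSE)
    }
    out[i, j] <- if (erode) all(vals) else any(vals)
  }
  out
}

naive_disk <- function(s) {
  r <- s %/% 2
  off <- expand.grid(dr = -r:r, dc = -r:r)
  keep <- off$dr^2 + off$dc^2 <= r^2
  list(dr = off$dr[keep], dc = off$dc[keep])
}

naive_opening <- function(mask, s) {
  se <- naive_disk(s)
  naive_morph(naive_morph(mask, se, TRUE), se, FALSE)
}

# BFS connected-component labeling in plain R
naive_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 8)
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  nxt <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] > 0L) next
    nxt <- nxt + 1L
    queue <- list(c(i, j)); lab[i, j] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nb))) {
        ii <- p[1] + nb[k, 1]; jj <- p[2] + nb[k, 2]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- nxt
          queue <- c(queue, list(c(ii, jj)))
        }
      }
    }
  }
  lab
}

# independent exhaustive double loop over (grid x images)
brute_force_adapt <- function(images, method, grid, criterion) {
  eff <- if (method == "otsu") "manual_threshold" else method
  vals <- matrix(0, nrow(grid), length(images))
  for (i in seq_len(nrow(grid))) for (j in seq_along(images)) {
    lab <- run_pipeline(images[[j]], c(grid$w[i], grid$t[i], grid$s[i]),
                        method = eff)
    vals[i, j] <- criterion$score(lab)
  }
  vals
}

brute_force_argmax <- function(grid, v) {
  idx <- which(v == max(v))
  idx[order(grid$t[idx], grid$w[idx], grid$s[idx])][1]
}

# small scene shared by adaptation tests (cheap, still bimodal + artifacts)
tiny_series <- function(B = 3, seed = 7, size = 96) {
  generate_series(default_scene(size = size, seed = seed), B = B)
}
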