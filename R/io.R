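#' @title Image and table input/output
#' @description Grayscale PNG (8-bit, via the `png` package) and plain-text
#'   PGM (P2, up to 16-bit) for images and label masks; CSV for tables; JSON
#'   and YAML for results and configuration. Label masks round-trip
#'   losslessly through PGM for up to 65535 objects.
#' @name cli_io
NULL

#' Read a grayscale image
#'
#' 8- or 16-bit input is rescaled to `[0, 1]` by the maximum representable
#' value (e.g. the 8-bit value 180 becomes 180/255). Color images and
#' unsupported formats are rejected rather than silently converted.
#'
#' @param path file path ending in `.png` or `.pgm`.
#' @return numeric matrix in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) {
      if (dim(img)[3] == 2L) img <- img[, , 1]  # gray + alpha
      else stop(sprintf("color images are not supported: %s", path),
                call. = FALSE)
    }
    img
  } else if (ext == "pgm") {
    p <- read_pgm(path)
    p$data / p$maxval
  } else {
    stop(sprintf("unsupported image format '.%s': %s", ext, path),
         call. = FALSE)
  }
}

#' Write a grayscale image
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param path `.png` (8-bit) or `.pgm` (16-bit plain text).
#' @param comment optional comment line embedded in PGM headers (used for
#'   provenance hashes).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, comment = NULL) {
  check_image(image)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(image, path)
  } else if (ext == "pgm") {
    write_pgm(round(image * 65535), path, maxval = 65535L, comment = comment)
  } else {
    stop(sprintf("unsupported image format '.%s'", ext), call. = FALSE)
  }
  invisible(path)
}

#' Write / read a label mask
#'
#' Masks are stored as plain-text PGM (P2) with `maxval` 65535, which
#' round-trips label values exactly.
#'
#' @param labels integer matrix (0 background).
#' @param path `.pgm` path.
#' @param comment optional PGM comment line.
#' @return `write_mask`: `path` invisibly; `read_mask`: integer matrix.
#' @export
write_mask <- function(labels, path, comment = NULL) {
  if (max(labels) > 65535L)
    stop("label masks support at most 65535 objects", call. = FALSE)
  if (tolower(tools::file_ext(path)) != "pgm")
    stop("label masks are written as .pgm", call. = FALSE)
  write_pgm(labels, path, maxval = 65535L, comment = comment)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  if (!file.exists(path))
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  p <- read_pgm(path)
  m <- p$data
  storage.mode(m) <- "integer"
  m
}

# Plain-text PGM (P2). Values are written row by row.
write_pgm <- function(values, path, maxval = 65535L, comment = NULL) {
  stopifnot(is.matrix(values))
  v <- round(values)
  if (any(v < 0) || any(v > maxval)) stop("PGM values out of range",
                                          call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("P2", con)
  if (!is.null(comment)) writeLines(paste("#", comment), con)
  writeLines(sprintf("%d %d", ncol(values), nrow(values)), con)
  writeLines(sprintf("%d", maxval), con)
  apply(v, 1, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}

read_pgm <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (lines[1] != "P2") stop("only plain (P2) PGM is supported", call. = FALSE)
  tokens <- as.numeric(unlist(strsplit(paste(lines[-1], collapse = " "),
                                       "[[:space:]]+")))
  tokens <- tokens[!is.na(tokens)]
  wh <- tokens[1:2]
  maxval <- tokens[3]
  data <- matrix(tokens[-(1:3)], nrow = wh[2], ncol = wh[1], byrow = TRUE)
  list(data = data, maxval = maxval)
}

#' Write a data frame as CSV with a provenance comment
#'
#' @param df data.frame.
#' @param path output `.csv` path.
#' @param comment optional `#`-prefixed header line (e.g. a config hash).
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste("#", comment), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  read.csv(path, comment.char = "#")
}

# Serialize a scene spec to a plain list (YAML/JSON friendly) and back.
spec_to_list <- function(spec) {
  list(scene_id = spec$scene_id, width = spec$width, height = spec$height,
       background = spec$background, seed = spec$seed,
       objects = lapply(spec$objects, function(o)
         list(shape = o$shape, class = o$class, center = o$center,
              size = o$size, intensity = o$intensity, angle = o$angle)))
}

spec_from_list <- function(x) {
  objects <- lapply(x$objects, function(o)
    scene_object(o$shape, class = o$class, center = unlist(o$center),
                 size = unlist(o$size), intensity = o$intensity,
                 angle = o$angle %||% 0))
  scene_spec(objects, width = x$width, height = x$height,
             background = x$background, scene_id = x$scene_id, seed = x$seed)
}

#' Write / load a benchmark series on disk
#'
#' The on-disk layout is all plain text: `clean.pgm`, `gt_labels.pgm`,
#' `gt_classes.csv`, `series_b01.pgm` ... , `levels.csv`
#' (`scene, b, n, A`), and `config.yaml` holding the scene spec, generation
#' parameters and a provenance hash.
#'
#' @param series a `benchmark_series`.
#' @param dir output directory (created if missing).
#' @return `write_series`: `dir` invisibly; `load_series`: a
#'   `benchmark_series`.
#' @export
write_series <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- list(spec = spec_to_list(series$spec), B = series$B, N = series$N,
              seed = series$seed, shading_max = series$shading_max,
              sigma_max = series$sigma_max, norm = series$norm)
  hash <- fnv1a(yaml::as.yaml(cfg))
  cfg$config_hash <- hash
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  write_image(series$clean, file.path(dir, "clean.pgm"), comment = hash)
  write_mask(series$gt$labels, file.path(dir, "gt_labels.pgm"),
             comment = hash)
  write_table(data.frame(object_id = seq_along(series$gt$classes),
                         class = series$gt$classes),
              file.path(dir, "gt_classes.csv"), comment = hash)
  for (b in seq_len(series$B))
    write_image(series$images[[b]],
                file.path(dir, sprintf("series_b%02d.pgm", b)),
                comment = hash)
  write_table(series$levels, file.path(dir, "levels.csv"), comment = hash)
  invisible(dir)
}

#' @rdname write_series
#' @export
load_series <- function(dir) {
  cfgf <- file.path(dir, "config.yaml")
  if (!file.exists(cfgf))
    stop(sprintf("input file not found: %s", cfgf), call. = FALSE)
  cfg <- yaml::read_yaml(cfgf)
  spec <- spec_from_list(cfg$spec)
  levels <- read_table(file.path(dir, "levels.csv"))
  images <- lapply(seq_len(cfg$B), function(b)
    read_image(file.path(dir, sprintf("series_b%02d.pgm", b))))
  classes <- read_table(file.path(dir, "gt_classes.csv"))$class
  gt <- ground_truth(read_mask(file.path(dir, "gt_labels.pgm")), classes)
  structure(list(spec = spec, clean = read_image(file.path(dir, "clean.pgm")),
                 gt = gt, images = images, levels = levels, norm = cfg$norm,
                 B = cfg$B, N = cfg$N, seed = cfg$seed,
                 shading_max = cfg$shading_max, sigma_max = cfg$sigma_max),
            class = "benchmark_series")
}
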