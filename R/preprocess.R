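# Deterministic normalization and seeded augmentation.  An image batch is a
# plain list: `pixels` — a (224, 224, 3, N) double array of normalized
# values — plus integer `labels` in [0, K) and `class_names`.

new_image_batch <- function(pixels, labels, class_names) {
  structure(list(pixels = pixels, labels = as.integer(labels),
                 class_names = class_names),
            class = "csb_image_batch")
}

#' @export
print.csb_image_batch <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image batch> %d images %dx%dx%d, %d classes (%s)\n",
              d[4], d[1], d[2], d[3], length(x$class_names),
              paste(x$class_names, collapse = ", ")))
  invisible(x)
}

batch_subset <- function(batch, idx) {
  new_image_batch(batch$pixels[, , , idx, drop = FALSE], batch$labels[idx],
                  batch$class_names)
}

batch_size <- function(batch) dim(batch$pixels)[4]

#' Normalize raw pixel values to [-1, 1]
#'
#' The affine map `x_norm = 2 * (x - x_min) / (x_max - x_min) - 1`, so the
#' encoding minimum maps to -1, the maximum to +1, and the midpoint to 0.
#' `(x_min, x_max)` default to the 8-bit encoding range (0, 255) rather than
#' per-image extremes, so brightness changes survive normalization.
#' `zero_one = TRUE` gives the plain `[0, 1]` variant
#' `(x - x_min) / (x_max - x_min)` for ablation.
#'
#' @param raw Numeric array/vector of raw pixel values.
#' @param x_min,x_max Encoding range; must satisfy `x_max > x_min`.
#' @param zero_one Map to `[0, 1]` instead of `[-1, 1]`.
#' @return Array of the same shape.
#' @export
normalize <- function(raw, x_min = 0, x_max = 255, zero_one = FALSE) {
  if (!(x_max > x_min)) {
    csb_stop("degenerate normalization range: x_max must exceed x_min",
             "csbnet_constant_image")
  }
  u <- (raw - x_min) / (x_max - x_min)
  if (zero_one) u else 2 * u - 1
}

#' Seeded flip/brightness augmentation
#'
#' Per image, independently: horizontal flip with probability `p_hflip`,
#' vertical flip with probability `p_vflip`, and brightness scaling by a
#' factor drawn uniformly from `brightness_factors` (default
#' `{0.7, 1, 1.3}`, i.e. 30% darkening / none / 30% brightening).
#' Brightness acts in raw pixel space — on `[-1, 1]` data the factor f maps
#' `x` to `f * (x + 1) - 1` — and the result is clipped back to `[-1, 1]`.
#' The same seed always produces bitwise-identical output; labels are
#' untouched.
#'
#' @param batch An image batch.
#' @param seed Integer seed, or `NULL` to consume the caller's RNG stream.
#' @param p_hflip,p_vflip Flip probabilities.
#' @param brightness_factors Candidate brightness factors; use `1` to
#'   disable brightness augmentation. Setting both probabilities to 0 and
#'   factors to `1` makes `augment()` the identity.
#' @return An image batch of the same shape.
#' @export
augment <- function(batch, seed = NULL, p_hflip = 0.5, p_vflip = 0.5,
                    brightness_factors = c(0.7, 1, 1.3)) {
  px <- batch$pixels
  d <- dim(px)
  with_seed(seed, {
    n <- d[4]
    hflip <- runif(n) < p_hflip
    vflip <- runif(n) < p_vflip
    bf <- brightness_factors[sample.int(length(brightness_factors), n, replace = TRUE)]
    for (i in seq_len(n)) {
      img <- px[, , , i]
      if (hflip[i]) img <- img[, d[2]:1, , drop = FALSE]
      if (vflip[i]) img <- img[d[1]:1, , , drop = FALSE]
      if (bf[i] != 1) img <- pmin(1, pmax(-1, bf[i] * (img + 1) - 1))
      px[, , , i] <- img
    }
  })
  new_image_batch(px, batch$labels, batch$class_names)
}

#' Load an image-folder dataset
#'
#' Reads the class-per-subdirectory layout: `root/<class>/<image>.png|jpg`.
#' Class order is the sorted subdirectory names; labels are the 0-based
#' class indices.  Images are decoded with EBImage, resized to
#' `size x size` (bilinear, antialiased), and normalized from (0, 255) to
#' `[-1, 1]` via [normalize()].  Grayscale images are replicated to 3
#' channels; undecodable files are skipped with a warning; an empty class
#' directory warns.
#'
#' @param root Dataset root directory.
#' @param size Target square size in pixels.
#' @return An image batch.
#' @export
load_image_folder <- function(root, size = 224L) {
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    csb_stop("load_image_folder() needs the EBImage package", "csbnet_io")
  }
  if (!dir.exists(root)) csb_stop(paste0("no such directory: ", root), "csbnet_io")
  classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  if (length(classes) == 0L) csb_stop("no class subdirectories found", "csbnet_io")
  imgs <- list(); labels <- integer(0)
  for (k in seq_along(classes)) {
    files <- sort(list.files(file.path(root, classes[k]),
                             pattern = "\\.(png|jpg|jpeg)$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0L) {
      warn(paste0("class directory is empty: ", classes[k]))
      next
    }
    for (f in files) {
      img <- tryCatch(EBImage::readImage(f), error = function(e) NULL)
      if (is.null(img)) {
        warn(paste0("skipping undecodable file: ", f))
        next
      }
      dm <- dim(img)
      if (length(dm) == 2L) img <- EBImage::Image(array(rep(img, 3), c(dm, 3)),
                                                  colormode = "Color")
      if (dim(img)[3] > 3L) img <- img[, , 1:3]   # drop alpha
      if (dm[1] != size || dm[2] != size) {
        img <- EBImage::resize(img, w = size, h = size, filter = "bilinear",
                               antialias = TRUE)
      }
      # EBImage stores (x, y, c) in [0, 1]; transpose to (row, col, c)
      a <- aperm(array(as.numeric(img), c(dim(img)[1], dim(img)[2], 3)), c(2, 1, 3))
      imgs[[length(imgs) + 1L]] <- normalize(a * 255)
      labels <- c(labels, k - 1L)
    }
  }
  if (length(imgs) == 0L) csb_stop("no decodable images found", "csbnet_io")
  px <- array(0, c(size, size, 3L, length(imgs)))
  for (i in seq_along(imgs)) px[, , , i] <- imgs[[i]]
  new_image_batch(px, labels, classes)
}
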