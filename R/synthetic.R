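# Seeded synthetic leaf-disease image generator.  A statistical stand-in for
# a 4-class maize leaf dataset: every image is a green elliptical leaf with
# vein texture on a neutral background, and each class adds its own lesion
# archetype — small gray rectangles (gray-leaf-spot-like), long tan streaks
# (northern-leaf-blight-like), dense small orange pustules (rust-like), or
# nothing (healthy).  Classes are separable by construction (lesion color
# and geometry), which is what makes the desk-scale learnability checks
# meaningful; no attempt is made at photorealism.

#' Synthetic dataset specification
#'
#' @param n_per_class Images per class.
#' @param classes Lesion archetypes to generate; the class names of the
#'   resulting batch. Supported archetypes: `"gray_rect_spots"`,
#'   `"tan_streaks"`, `"rust_pustules"`, `"healthy"`.
#' @param seed Integer master seed; each image derives its own sub-seed, so
#'   identical specs yield bitwise-identical datasets.
#' @param lesion_density Multiplier on per-class lesion counts (> 0); lower
#'   values make the classes harder to tell apart.
#' @param lesion_contrast Multiplier in (0, 1] on the lesion-vs-leaf color
#'   contrast.
#' @param color_jitter Standard deviation (in 8-bit units) of per-lesion
#'   color jitter.
#' @param leaf_hue_range Range of the green-channel base value of the leaf
#'   blade (8-bit units).
#' @return A `csb_synthetic_spec` list.
#' @export
synthetic_spec <- function(n_per_class = 50L,
                           classes = c("gray_rect_spots", "healthy",
                                       "rust_pustules", "tan_streaks"),
                           seed = 1L,
                           lesion_density = 1,
                           lesion_contrast = 1,
                           color_jitter = 8,
                           leaf_hue_range = c(110, 150)) {
  known <- c("gray_rect_spots", "tan_streaks", "rust_pustules", "healthy")
  bad <- setdiff(classes, known)
  if (length(bad)) {
    csb_stop(paste0("unknown lesion archetype(s): ", paste(bad, collapse = ", ")),
             "csbnet_bad_config")
  }
  if (anyDuplicated(classes)) csb_stop("archetypes must be distinct", "csbnet_bad_config")
  if (lesion_density <= 0 || lesion_contrast <= 0 || lesion_contrast > 1) {
    csb_stop("`lesion_density` must be > 0 and `lesion_contrast` in (0, 1]",
             "csbnet_bad_config")
  }
  structure(list(n_per_class = assert_count(n_per_class, "n_per_class"),
                 classes = classes, seed = assert_count(seed, "seed", min = 0L),
                 lesion_density = lesion_density, lesion_contrast = lesion_contrast,
                 color_jitter = color_jitter, leaf_hue_range = leaf_hue_range),
            class = "csb_synthetic_spec")
}

# precomputed pixel-offset discs for the pustule radii
.disc_offsets <- lapply(1:3, function(rad) {
  dd <- expand.grid(dr = -rad:rad, dc = -rad:rad)
  dd[dd$dr^2 + dd$dc^2 <= rad^2, ]
})

# one raw 8-bit image (224 x 224 x 3 integer array) + lesion count
synth_one_image <- function(class, spec) {
  S <- 224L
  rows <- matrix(seq_len(S), S, S)
  cols <- matrix(seq_len(S), S, S, byrow = TRUE)
  jit <- spec$color_jitter
  # neutral background with mild noise
  img <- array(0, c(S, S, 3L))
  base_bg <- c(150, 140, 125)
  for (ch in 1:3) img[, , ch] <- base_bg[ch] + rnorm(S * S, sd = 5)
  # elliptical leaf blade
  cx <- 112 + runif(1, -8, 8); cy <- 112 + runif(1, -8, 8)
  a <- runif(1, 80, 100); b <- runif(1, 52, 68)
  theta <- runif(1, -0.35, 0.35)
  u <- (rows - cx) * cos(theta) + (cols - cy) * sin(theta)
  v <- -(rows - cx) * sin(theta) + (cols - cy) * cos(theta)
  leaf <- (u / a)^2 + (v / b)^2 <= 1
  g0 <- runif(1, spec$leaf_hue_range[1], spec$leaf_hue_range[2])
  leaf_col <- c(0.45 * g0, g0, 0.38 * g0)
  grad <- 1 + 0.12 * (v / b)                       # gentle gradient along the blade
  vein <- 1 - 0.18 * (abs(v) < 1.6) - 0.10 * (abs(sin(u / 9)) < 0.12)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[leaf] <- (leaf_col[ch] * grad * vein)[leaf] + rnorm(sum(leaf), sd = 4)
    img[, , ch] <- plane
  }
  leaf_idx <- which(leaf)
  n_lesions <- 0L
  # lesions are collected as (pixel mask, jittered color) and painted in one
  # pass per channel, which keeps full-plane copies to three total
  masks <- list(); lcols <- list()
  paint_patch <- function(img, mask_idx, col) {
    masks[[length(masks) + 1L]] <<- mask_idx
    lcols[[length(lcols) + 1L]] <<- col + rnorm(3, sd = jit)
    img
  }
  if (class == "gray_rect_spots" && length(leaf_idx)) {
    n_lesions <- max(1L, round(spec$lesion_density * (8 + rpois(1, 5))))
    for (i in seq_len(n_lesions)) {
      ctr <- leaf_idx[sample.int(length(leaf_idx), 1L)]
      r0 <- ((ctr - 1L) %% S) + 1L; c0 <- ((ctr - 1L) %/% S) + 1L
      h <- sample(5:12, 1L); w <- sample(4:9, 1L)
      rs <- pmin(pmax(r0:(r0 + h), 1L), S); cs <- pmin(pmax(c0:(c0 + w), 1L), S)
      mask <- as.vector(outer(rs, (cs - 1L) * S, "+"))
      img <- paint_patch(img, mask, c(148, 138, 112))
    }
  } else if (class == "tan_streaks" && length(leaf_idx)) {
    n_lesions <- max(1L, round(spec$lesion_density * (4 + rpois(1, 2))))
    for (i in seq_len(n_lesions)) {
      ctr <- leaf_idx[sample.int(length(leaf_idx), 1L)]
      r0 <- ((ctr - 1L) %% S) + 1L; c0 <- ((ctr - 1L) %/% S) + 1L
      len <- sample(50:110, 1L); wid <- sample(3:6, 1L)
      slope <- runif(1, -0.25, 0.25)
      rr <- round(seq(r0 - len / 2, r0 + len / 2))
      cc <- round(c0 + slope * (rr - r0))
      keep <- rr >= 1L & rr <= S & cc >= 1L & cc + wid <= S
      rr <- rr[keep]; cc <- cc[keep]
      if (!length(rr)) next
      mask <- unlist(lapply(0:(wid - 1L), function(o) rr + (cc + o - 1L) * S))
      img <- paint_patch(img, mask, c(185, 155, 92))
    }
  } else if (class == "rust_pustules" && length(leaf_idx)) {
    n_lesions <- max(1L, round(spec$lesion_density * (60 + rpois(1, 15))))
    for (i in seq_len(n_lesions)) {
      ctr <- leaf_idx[sample.int(length(leaf_idx), 1L)]
      r0 <- ((ctr - 1L) %% S) + 1L; c0 <- ((ctr - 1L) %/% S) + 1L
      rad <- sample(1:3, 1L)
      dd <- .disc_offsets[[rad]]
      rr <- pmin(pmax(r0 + dd$dr, 1L), S); cc <- pmin(pmax(c0 + dd$dc, 1L), S)
      img <- paint_patch(img, rr + (cc - 1L) * S, c(196, 92, 28))
    }
  }
  if (length(masks)) {
    ct <- spec$lesion_contrast
    for (ch in 1:3) {
      plane <- img[, , ch]
      for (li in seq_along(masks)) {
        plane[masks[[li]]] <- (1 - ct) * plane[masks[[li]]] + ct * lcols[[li]][ch]
      }
      img[, , ch] <- plane
    }
  }
  list(img = pmin(pmax(round(img), 0), 255), n_lesions = n_lesions)
}

#' Generate a synthetic leaf-disease image batch
#'
#' Produces `n_per_class` images for each archetype in the spec, already
#' normalized to `[-1, 1]`, together with a manifest recording each image's
#' class, derived seed and lesion count.  Identical specs yield
#' bitwise-identical datasets because every image draws from its own derived
#' seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `batch` (an image batch) and `manifest` (a tibble:
#'   image, class, label, seed, n_lesions).
#' @examples
#' \donttest{
#' ds <- generate_leaves(synthetic_spec(n_per_class = 2, seed = 7))
#' ds$manifest
#' }
#' @export
generate_leaves <- function(spec) {
  stopifnot(inherits(spec, "csb_synthetic_spec"))
  classes <- spec$classes
  n <- spec$n_per_class * length(classes)
  px <- array(0, c(224L, 224L, 3L, n))
  labels <- integer(n)
  rows <- vector("list", n)
  base <- derive_seed(spec$seed, "synth")
  i <- 0L
  for (k in seq_along(classes)) {
    for (j in seq_len(spec$n_per_class)) {
      i <- i + 1L
      img_seed <- as.integer((as.numeric(base) + 131071 * (i - 1L)) %% 2147483629)
      one <- with_seed(img_seed, synth_one_image(classes[k], spec))
      px[, , , i] <- normalize(one$img)
      labels[i] <- k - 1L
      rows[[i]] <- tibble::tibble(image = sprintf("%s_%04d", classes[k], j),
                                  class = classes[k], label = k - 1L,
                                  seed = img_seed, n_lesions = one$n_lesions)
    }
  }
  list(batch = new_image_batch(px, labels, classes),
       manifest = dplyr::bind_rows(rows))
}

#' Export a batch as an image-folder tree
#'
#' Writes 8-bit PNGs (lossless) in the class-per-subdirectory layout that
#' [load_image_folder()] reads, plus a `manifest.json` alongside.  An empty
#' batch produces the empty tree with a warning.
#'
#' @param batch An image batch.
#' @param manifest Tibble from [generate_leaves()] (optional; a minimal one
#'   is derived from the labels if missing).
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
export_leaves <- function(batch, manifest = NULL, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n <- batch_size(batch)
  if (is.null(manifest)) {
    manifest <- tibble::tibble(
      image = sprintf("%s_%04d", batch$class_names[batch$labels + 1L], seq_len(max(n, 0L))),
      class = batch$class_names[batch$labels + 1L],
      label = batch$labels, seed = NA_integer_, n_lesions = NA_integer_)
  }
  for (cl in batch$class_names) {
    dir.create(file.path(out_dir, cl), showWarnings = FALSE)
  }
  if (n == 0L) {
    warn("exporting an empty batch: writing directory tree and manifest only")
  }
  for (i in seq_len(n)) {
    img01 <- (batch$pixels[, , , i] + 1) / 2
    path <- file.path(out_dir, manifest$class[i], paste0(manifest$image[i], ".png"))
    ok <- tryCatch({ png::writePNG(img01, path); TRUE },
                   error = function(e) {
                     csb_stop(sprintf("failed writing %s: %s", path, conditionMessage(e)),
                              "csbnet_io")
                   })
  }
  jsonlite::write_json(as.data.frame(manifest), file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
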