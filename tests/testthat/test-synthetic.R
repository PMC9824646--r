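test_that("generation is balanced, deterministic under the seed, and labeled", {
  spec <- synthetic_spec(n_per_class = 5, seed = 77)
  ds1 <- generate_leaves(spec)
  expect_identical(dim(ds1$batch$pixels), c(224L, 224L, 3L, 20L))
  expect_identical(as.vector(table(ds1$batch$labels)), rep(5L, 4))
  expect_identical(nrow(ds1$manifest), 20L)
  ds2 <- generate_leaves(synthetic_spec(n_per_class = 5, seed = 77))
  expect_identical(ds1$batch$pixels, ds2$batch$pixels)
  expect_identical(ds1$manifest, ds2$manifest)
  ds3 <- generate_leaves(synthetic_spec(n_per_class = 5, seed = 78))
  expect_false(identical(ds1$batch$pixels, ds3$batch$pixels))
  expect_error(synthetic_spec(classes = c("healthy", "blotches")),
               class = "csbnet_bad_config")
})

test_that("pixels are valid normalized 8-bit values", {
  ds <- generate_leaves(synthetic_spec(n_per_class = 2, seed = 3))
  px <- ds$batch$pixels
  expect_true(all(px >= -1 & px <= 1))
  # 8-bit grid: every value is 2*k/255 - 1 for integer k
  k <- (px + 1) / 2 * 255
  expect_equal(k, round(k), tolerance = 1e-9)
})

test_that("class color statistics separate by construction", {
  ds <- generate_leaves(synthetic_spec(n_per_class = 8, seed = 5))
  b <- ds$batch
  mean_chan <- function(lbl, ch) {
    idx <- which(b$labels == lbl)
    mean(b$pixels[, , ch, idx])
  }
  rust <- match("rust_pustules", b$class_names) - 1L
  healthy <- match("healthy", b$class_names) - 1L
  tan <- match("tan_streaks", b$class_names) - 1L
  # rust pustules add red mass relative to healthy leaves
  expect_gt(mean_chan(rust, 1) - mean_chan(healthy, 1), 0.02)
  # and shift the red-green balance (orange on green is red-dominant)
  rg <- function(lbl) mean_chan(lbl, 1) - mean_chan(lbl, 2)
  expect_gt(rg(rust) - rg(healthy), 0.02)
  # tan streaks brighten red too but with distinct geometry; at minimum the
  # diseased classes all differ from healthy in red-channel mass
  expect_gt(mean_chan(tan, 1) - mean_chan(healthy, 1), 0.01)
})

test_that("a linear classifier on mean-channel features separates rust from healthy", {
  ds <- generate_leaves(synthetic_spec(n_per_class = 30, seed = 13))
  b <- ds$batch
  keep <- b$labels %in% (match(c("rust_pustules", "healthy"), b$class_names) - 1L)
  feats <- t(apply(b$pixels[, , , keep, drop = FALSE], 4, function(a)
    c(mean(a[, , 1]), mean(a[, , 2]), mean(a[, , 3]))))
  y <- as.integer(b$labels[keep] == (match("rust_pustules", b$class_names) - 1L))
  set.seed(1)
  tr <- sample(length(y), length(y) / 2)
  fit <- suppressWarnings(
    stats::glm(y ~ ., data = data.frame(feats, y = y), subset = tr,
               family = stats::binomial()))
  pred <- as.integer(stats::predict(fit, newdata = data.frame(feats)[-tr, ],
                                    type = "response") > 0.5)
  expect_gt(mean(pred == y[-tr]), 0.95)
})

test_that("export/load round-trips the folder layout and manifest", {
  ds <- generate_leaves(synthetic_spec(n_per_class = 2, seed = 19))
  root <- withr::local_tempdir()
  export_leaves(ds$batch, ds$manifest, root)
  expect_setequal(list.dirs(root, recursive = FALSE, full.names = FALSE),
                  ds$batch$class_names)
  man <- jsonlite::read_json(file.path(root, "manifest.json"), simplifyVector = TRUE)
  expect_identical(nrow(man), 8L)
  expect_identical(man$class, ds$manifest$class)
  pngs <- list.files(root, pattern = "\\.png$", recursive = TRUE)
  expect_length(pngs, 8L)
  # empty batch: tree + manifest with a warning
  empty <- csbnet:::new_image_batch(array(0, c(224, 224, 3, 0)), integer(0),
                                    c("a", "b"))
  root2 <- withr::local_tempdir()
  expect_warning(export_leaves(empty, NULL, root2), "empty")
  expect_setequal(list.dirs(root2, recursive = FALSE, full.names = FALSE), c("a", "b"))
  expect_true(file.exists(file.path(root2, "manifest.json")))
})

test_that("generating 400 images completes within the time budget", {
  t0 <- Sys.time()
  ds <- generate_leaves(synthetic_spec(n_per_class = 100, seed = 55))
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  expect_identical(dim(ds$batch$pixels)[4], 400L)
  expect_lt(elapsed, 60)
})
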