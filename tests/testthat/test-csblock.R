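test_that("measurement map shapes follow the conv shape arithmetic", {
  # floor((n + 2p - k)/s) + 1 layerwise: 224 -> 112 -> 56 -> 28 -> 28*factor
  cfg <- model_config(sr = 0.5, num_classes = 4)
  x <- array(rnorm(224 * 224 * 3 * 1), c(224, 224, 3, 1))
  mm <- cs_block_forward(x, cfg, seed = 2)
  expect_identical(dim(mm$pre), c(28L, 28L, 96L, 1L))
  expect_identical(dim(mm$post), c(56L, 56L, 96L, 1L))
  expect_equal(mm$effective_sr, 0.5)
  expect_error(cs_block_forward(array(0, c(128, 128, 3, 1)), cfg),
               class = "csbnet_shape")
})

test_that("the CS-Block is affine: zero input gives the bias response, scaling is exact", {
  cfg <- model_config(sr = 0.1, num_classes = 4)
  x0 <- array(0, c(224, 224, 3, 1))
  x <- array(rnorm(224 * 224 * 3), c(224, 224, 3, 1))
  f0 <- cs_block_forward(x0, cfg, seed = 7)$pre
  fx <- cs_block_forward(x, cfg, seed = 7)$pre
  fax <- cs_block_forward(2.5 * x, cfg, seed = 7)$pre
  # bias response is content-independent; homogeneity of the linear part
  expect_equal(fax - f0, 2.5 * (fx - f0), tolerance = 1e-9)
  # additivity on a second input
  y <- array(rnorm(224 * 224 * 3), c(224, 224, 3, 1))
  fy <- cs_block_forward(y, cfg, seed = 7)$pre
  fxy <- cs_block_forward(x + y, cfg, seed = 7)$pre
  expect_equal(fxy - f0, (fx - f0) + (fy - f0), tolerance = 1e-9)
})

test_that("the stacked convolutions equal one explicit measurement matrix on a 16x16 toy", {
  # materialize the matrix column by column from basis responses, then compare
  set.seed(99)
  layers <- list(
    ns$layer_conv("c1", 3L, 2L, 1L, 3L, 6L),
    ns$layer_conv("c2", 3L, 2L, 1L, 6L, 6L),
    ns$layer_conv("c3", 3L, 2L, 1L, 6L, 6L),
    ns$layer_conv("proj", 1L, 1L, 0L, 6L, 4L)
  )
  layers <- lapply(layers, ns$init_layer)
  fwd <- function(x) as.vector(ns$run_layers(layers, array(x, c(16, 16, 3, 1))))
  d_in <- 16 * 16 * 3
  b0 <- fwd(numeric(d_in))
  M <- matrix(0, length(b0), d_in)
  for (i in seq_len(d_in)) {
    e <- numeric(d_in); e[i] <- 1
    M[, i] <- fwd(e) - b0
  }
  set.seed(100)
  for (rep in 1:3) {
    x <- rnorm(d_in)
    expect_equal(fwd(x), as.vector(M %*% x + b0), tolerance = 1e-10)
  }
})

test_that("CS-Block parameter count matches the closed form 75648 + 65 X", {
  for (sr in c(0.05, 0.7, 1.0)) {
    cfg <- model_config(sr = sr)
    expect_identical(cs_block_param_count(cfg), 75648L + 65L * cfg$X)
  }
  expect_identical(cs_block_param_count(model_config(sr = 0.7)), 84358L)
  expect_identical(cs_block_param_count(model_config(sr = 1.0)), 88128L)
  # X = 1 floor case: nothing below one channel
  tiny <- model_config(sr = 1 / 192)
  expect_identical(tiny$X, 1L)
  expect_identical(cs_block_param_count(tiny), 75713L)
})

test_that("up-sampling adds no trainable parameters and replicates nearest neighbours", {
  lg <- count_params(model_config(sr = 0.5))
  expect_identical(lg$params[lg$layer == "upsample"], 0L)
  up <- ns$layer_upsample("u", 2L)
  x <- array(1:8, c(2, 2, 2, 1))
  out <- ns$layer_forward(up, x)$out
  expect_identical(dim(out), c(4L, 4L, 2L, 1L))
  expect_equal(out[1, 1, 1, 1], out[2, 2, 1, 1])
  expect_equal(out[c(1, 2), c(1, 2), , ], out[c(2, 1), c(2, 1), , ])
})

test_that("pre-upsample element count over input equals X/192 across the SR grid", {
  x <- array(rnorm(224 * 224 * 3), c(224, 224, 3, 1))
  for (sr in c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7)) {
    cfg <- model_config(sr = sr)
    mm <- cs_block_forward(x, cfg, seed = 1)
    expect_equal(length(mm$pre) / length(x), cfg$X / 192)
  }
})
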