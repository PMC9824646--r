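test_that("cross-entropy closed forms: perfect prediction and uniform guess", {
  expect_equal(cross_entropy(c(1, 0, 0, 0), c(1, 0, 0, 0)), 0)
  expect_equal(cross_entropy(c(1, 0, 0, 0), rep(0.25, 4)), log(4))
  expect_equal(cross_entropy(c(0, 1, 0, 0), rep(0.25, 4)), -log(0.25))
  expect_error(cross_entropy(c(1, 0), c(0.5, 0.4, 0.1)), class = "csbnet_bad_input")
  expect_error(cross_entropy(c(0.5, 0.6), c(0.5, 0.5)), class = "csbnet_bad_input")
  # the epsilon floor keeps H finite where q = 0 under p > 0
  expect_true(is.finite(cross_entropy(c(1, 0), c(0, 1))))
})

test_that("Gibbs' inequality H(p,q) >= H(p,p) on random 4-class distributions", {
  set.seed(17)
  for (i in 1:200) {
    p <- stats::rgamma(4, 1); p <- p / sum(p)
    q <- stats::rgamma(4, 1); q <- q / sum(q)
    expect_gte(cross_entropy(p, q) + 1e-12, cross_entropy(p, p))
  }
})

test_that("training with zero learning rate leaves the weights unchanged", {
  b <- tiny_batch(n_per_class = 2, seed = 31)
  # dropout off so minibatch losses are deterministic given the weights
  net <- build_network(model_config(sr = 0.05, num_classes = 4, dropout_p = 0), seed = 1)
  tc0 <- train_config(learning_rate = 0, epochs = 1, batch_size = 8, seed = 1)
  fit <- train(net, b, val_batch = NULL, tc = tc0, augment_train = FALSE)
  w_before <- net$layers[[1]]$params$W
  w_after <- fit$network$layers[[1]]$params$W
  expect_identical(w_after, w_before)
  # and the recorded loss is the loss of the untouched network
  fw <- ns$net_forward(net, b$pixels)
  expect_equal(fit$history$train_loss[1],
               ns$softmax_xent(fw$scores, b$labels)$loss, tolerance = 1e-6)
})

test_that("same seed reproduces the identical first-epoch loss; empty data errors", {
  b <- tiny_batch(n_per_class = 2, seed = 32)
  tc <- train_config(epochs = 1, batch_size = 4, seed = 7)
  f1 <- train(build_network(model_config(sr = 0.05), seed = 2), b, NULL, tc)
  f2 <- train(build_network(model_config(sr = 0.05), seed = 2), b, NULL, tc)
  expect_identical(f1$history$train_loss[1], f2$history$train_loss[1])
  empty <- csbnet:::new_image_batch(array(0, c(224, 224, 3, 0)), integer(0), "x")
  expect_error(train(build_network(model_config(sr = 0.05), seed = 2), empty, NULL, tc),
               class = "csbnet_bad_input")
})

test_that("every trainable parameter group receives gradient on a random batch", {
  set.seed(8)
  b <- tiny_batch(n_per_class = 1, seed = 33)
  for (attn in c("se", "eca", "cbam")) {
    net <- build_network(model_config(sr = 0.05, num_classes = 4, attention = attn),
                         seed = 3)
    fw <- ns$net_forward(net, b$pixels, training = FALSE, with_caches = TRUE)
    sx <- ns$softmax_xent(fw$scores, b$labels)
    grads <- ns$net_backward(net, fw$caches, sx$dscores)
    for (i in seq_along(grads)) {
      for (nm in names(grads[[i]])) {
        expect_gt(sum(abs(grads[[i]][[nm]])), 0,
                  label = sprintf("grad norm of %s/%s (%s)",
                                  net$layers[[i]]$name, nm, attn))
      }
    }
  }
})

test_that("label width is validated against the network output", {
  b <- tiny_batch(n_per_class = 1, seed = 34)
  net3 <- build_network(model_config(sr = 0.05, num_classes = 3), seed = 1)
  expect_error(train(net3, b, NULL, train_config(epochs = 1)),
               class = "csbnet_bad_input")
})

test_that("sweep table harness: two-point sweep yields finite sorted rows", {
  tr <- generate_leaves(synthetic_spec(n_per_class = 4, seed = 41))
  va <- generate_leaves(synthetic_spec(n_per_class = 2, seed = 42))
  tc <- train_config(epochs = 1, batch_size = 8, seed = 5)
  tbl <- suppressWarnings(
    sr_sweep(c(0.7, 0.1), tr$batch, va$batch, tc, model_config(num_classes = 4)))
  expect_identical(nrow(tbl), 2L)
  expect_identical(tbl$sr, c(0.1, 0.7))
  expect_identical(tbl$X, c(19L, 134L))
  expect_true(all(is.finite(tbl$accuracy)))
  expect_true(all(tbl$accuracy >= 0 & tbl$accuracy <= 1))
  expect_s3_class(tbl, "csb_sweep")
  # trend statistic is defined (ties count as a flat trend, not NA)
  expect_true(is.finite(sweep_trend(tbl)))
})

test_that("history tidiers and the default SR grid match the experimental protocol", {
  expect_identical(eval(formals(sr_sweep)$srs),
                   c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7))
  h <- tibble::tibble(epoch = 1:2, train_loss = c(1.2, 1.0), val_accuracy = c(0.4, 0.6))
  fit <- structure(list(history = h, metrics = NULL), class = "csbnet_fit")
  expect_identical(tidy(fit), h)
  expect_equal(glance(fit)$best_val_accuracy, 0.6)
})
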