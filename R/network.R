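# CSBNet assembly: CS-Block -> AlexNet-derived feature extractor -> channel
# attention -> 3-layer fully connected classifier.

feature_layers <- function(config) {
  fw <- config$feat_widths
  list(
    layer_conv("feat_conv1", k = 7L, stride = 4L, pad = 3L,
               c_in = config$X, c_out = config$first_feat_filters, activation = "relu"),
    layer_maxpool("pool1", k = 3L, stride = 2L),
    layer_conv("feat_conv2", k = 5L, stride = 1L, pad = 2L,
               c_in = config$first_feat_filters, c_out = fw[1], activation = "relu"),
    layer_maxpool("pool2", k = 3L, stride = 2L),
    layer_conv("feat_conv3", k = 3L, stride = 1L, pad = 1L,
               c_in = fw[1], c_out = fw[2], activation = "relu"),
    layer_conv("feat_conv4", k = 3L, stride = 1L, pad = 1L,
               c_in = fw[2], c_out = fw[3], activation = "relu"),
    layer_conv("feat_conv5", k = 3L, stride = 1L, pad = 1L,
               c_in = fw[3], c_out = fw[4], activation = "relu"),
    layer_adaptive_avgpool("pool3_adaptive", out = 2L)
  )
}

attention_layers <- function(config) {
  C <- config$feat_widths[4]
  switch(config$attention,
    none = list(),
    se = list(layer_se("se", C, config$se_reduction)),
    eca = list(layer_eca("eca", C, config$eca_gamma, config$eca_b)),
    cbam = list(layer_cbam("cbam", C, config$se_reduction, config$cbam_spatial_kernel))
  )
}

classifier_layers <- function(config) {
  fd <- config$fc_dims
  list(
    layer_flatten("flatten"),
    layer_dropout("dropout1", config$dropout_p),
    layer_fc("fc1", fd[1], fd[2], activation = "relu"),
    layer_dropout("dropout2", config$dropout_p),
    layer_fc("fc2", fd[2], fd[3], activation = "relu"),
    layer_dropout("dropout3", config$dropout_p),
    layer_fc("fc3", fd[3], config$num_classes)
  )
}

#' Build a CSBNet network
#'
#' Assembles the full model: CS-Block (learned measurement operator),
#' feature extractor (7x7 stride-4 convolution with 48 filters, two 3x3
#' stride-2 max-pools, 5 convolutions in total, adaptive average pooling to
#' 2x2), optional channel-attention stage on the 128-channel feature map, and
#' the 512 -> 1024 -> 2048 -> K classifier with 50% dropout.  Weights are
#' drawn from a seeded stream so the same seed always yields the same network.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `csbnet_model`.
#' @examples
#' net <- build_network(model_config(sr = 0.5, num_classes = 4), seed = 1)
#' net
#' @export
build_network <- function(config, seed = 1L) {
  stopifnot(inherits(config, "csb_model_config"))
  layers <- c(cs_block_layers(config), feature_layers(config),
              attention_layers(config), classifier_layers(config))
  layers <- with_seed(derive_seed(seed, "init"), lapply(layers, init_layer))
  structure(list(config = config, layers = layers, seed = as.integer(seed)),
            class = "csbnet_model")
}

#' @export
print.csbnet_model <- function(x, ...) {
  lg <- count_params(x)
  cat(sprintf("<csbnet model> SR %.4g (X = %d), %d classes, attention: %s\n",
              unclass(x$config$sr), x$config$X, x$config$num_classes,
              x$config$attention))
  cat(sprintf("  %d layers, %s trainable parameters (%.2f MB float32)\n",
              length(x$layers), format(attr(lg, "total"), big.mark = ","),
              attr(lg, "params_size_mb")))
  invisible(x)
}

# Full forward pass; with_caches = TRUE also returns what backward needs.
net_forward <- function(net, x, training = FALSE, with_caches = FALSE) {
  caches <- if (with_caches) vector("list", length(net$layers)) else NULL
  for (i in seq_along(net$layers)) {
    fw <- layer_forward(net$layers[[i]], x, training = training)
    x <- fw$out
    if (with_caches) caches[[i]] <- fw$cache
  }
  list(scores = x, caches = caches)
}

# Backward pass from score gradients; returns per-layer grads and accumulates
# nothing (the optimizer owns state).
net_backward <- function(net, caches, dscores) {
  grads <- vector("list", length(net$layers))
  d <- dscores
  for (i in rev(seq_along(net$layers))) {
    bw <- layer_backward(net$layers[[i]], caches[[i]], d)
    d <- bw$dx
    grads[[i]] <- bw$grads
  }
  grads
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

#' Predict class scores and labels
#'
#' @param object A `csbnet_model`.
#' @param batch An image batch (list with `pixels`, `labels`, `class_names`)
#'   or a bare pixel array.
#' @param ... Unused.
#' @return A tibble with one row per image: predicted class index (0-based),
#'   predicted class name when known, and per-class softmax probabilities in
#'   a list-column.
#' @export
predict.csbnet_model <- function(object, batch, ...) {
  x <- if (is.list(batch)) batch$pixels else batch
  scores <- net_forward(object, x)$scores
  probs <- softmax_cols(scores)
  pred <- max.col(t(probs), ties.method = "first") - 1L
  class_names <- if (is.list(batch)) batch$class_names else NULL
  tibble::tibble(
    predicted = pred,
    predicted_class = if (!is.null(class_names)) class_names[pred + 1L] else NA_character_,
    prob = purrr::map(seq_len(ncol(probs)), ~ probs[, .x])
  )
}

# parameter accounting ---------------------------------------------------------

layer_ledger_row <- function(layer) {
  kernel <- switch(layer$type,
    conv = sprintf("%dx%d/s%d", layer$k, layer$k, layer$stride),
    fc = "dense",
    se = "gap+2fc",
    eca = sprintf("1d-conv k%d", layer$k),
    cbam = "mlp+conv",
    maxpool = sprintf("max %dx%d/s%d", layer$k, layer$k, layer$stride),
    adaptpool = sprintf("adaptive-avg %dx%d", layer$out, layer$out),
    upsample = sprintf("nearest x%d", layer$factor),
    "-"
  )
  io <- switch(layer$type,
    conv = c(layer$c_in, layer$c_out),
    fc = c(layer$d_in, layer$d_out),
    se = ,
    eca = ,
    cbam = c(layer$channels, layer$channels),
    c(NA_integer_, NA_integer_)
  )
  nm <- layer$name; ty <- layer$type; np <- as.integer(layer_param_count(layer))
  tibble::tibble(layer = nm, type = ty, kernel = kernel,
                 in_dim = io[1], out_dim = io[2], params = np)
}

#' Per-layer trainable-parameter ledger
#'
#' Exact integer accounting: `(kh*kw*C_in + 1)*C_out` for biased convolutions,
#' `(d_in + 1)*d_out` for biased dense layers; pooling, up-sampling and
#' dropout contribute nothing.  The ledger depends only on the architecture,
#' never on weight values.
#'
#' @param net A `csbnet_model` (or a [model_config()], which is built into an
#'   unfitted network first).
#' @return A tibble of class `csb_param_ledger` with one row per layer and
#'   attributes `total` (integer) and `params_size_mb` (float32 accounting,
#'   `total * 4 / 2^20`, rounded to 2 decimals).
#' @examples
#' lg <- count_params(model_config(sr = 0.7, num_classes = 4))
#' attr(lg, "total")
#' @export
count_params <- function(net) {
  if (inherits(net, "csb_model_config")) net <- build_network(net, seed = 1L)
  stopifnot(inherits(net, "csbnet_model"))
  ledger <- dplyr::bind_rows(lapply(net$layers, layer_ledger_row))
  total <- sum(ledger$params)
  structure(ledger,
            class = c("csb_param_ledger", class(ledger)),
            total = total,
            params_size_mb = round(total * 4 / 2^20, 2))
}

#' @export
print.csb_param_ledger <- function(x, ...) {
  NextMethod()
  cat(sprintf("# total: %s params | %.2f MB (float32)\n",
              format(attr(x, "total"), big.mark = ","), attr(x, "params_size_mb")))
  invisible(x)
}

#' Write a parameter ledger to CSV or JSON
#'
#' @param ledger A [count_params()] result.
#' @param path Output path; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_ledger <- function(ledger, path) {
  stopifnot(inherits(ledger, "csb_param_ledger"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(layers = as.data.frame(ledger), total = attr(ledger, "total"),
           params_size_mb = attr(ledger, "params_size_mb")),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    write.csv(as.data.frame(ledger), path, row.names = FALSE)
  }
  invisible(path)
}

# checkpointing ----------------------------------------------------------------

#' Save / load a model checkpoint
#'
#' A checkpoint is a single RDS file holding the weights together with the
#' embedded [model_config()], so a saved model can always be rebuilt and
#' evaluated without external context.
#'
#' @param net A `csbnet_model`.
#' @param path Checkpoint file path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   restored `csbnet_model`.
#' @export
save_model <- function(net, path) {
  stopifnot(inherits(net, "csbnet_model"))
  saveRDS(net, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  net <- readRDS(path)
  if (!inherits(net, "csbnet_model")) csb_stop("not a csbnet checkpoint", "csbnet_io")
  net
}
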