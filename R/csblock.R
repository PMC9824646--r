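# The CS-Block: the learned measurement operator that replaces the sensing
# matrix of classical compressed sensing.  Three 3x3 stride-2 convolutions
# (3 -> 64 -> 64 -> 64) halve 224 to 112/56/28, a 1x1 convolution projects to
# X = 192 * SR channels, and a nearest-neighbour up-sampling stage enlarges
# the map so the downstream 7x7 convolution always has support.  There is
# deliberately NO nonlinearity inside the block: the composite of the four
# convolutions is a single affine operator y = Ax + b on the flattened image,
# which is exactly what lets it stand in for a measurement matrix.  The
# element-count ratio of the pre-upsample map to the input is X / 192 — the
# effective sensing rate.

cs_block_layers <- function(config) {
  w <- config$cs_widths
  list(
    layer_conv("cs_conv1", k = 3L, stride = 2L, pad = 1L, c_in = 3L, c_out = w[1]),
    layer_conv("cs_conv2", k = 3L, stride = 2L, pad = 1L, c_in = w[1], c_out = w[2]),
    layer_conv("cs_conv3", k = 3L, stride = 2L, pad = 1L, c_in = w[2], c_out = w[3]),
    layer_conv("cs_project", k = 1L, stride = 1L, pad = 0L, c_in = w[3], c_out = config$X),
    layer_upsample("upsample", factor = config$upsample_factor)
  )
}

# Runs a list of layers in inference mode; returns the final output.
run_layers <- function(layers, x) {
  for (l in layers) x <- layer_forward(l, x, training = FALSE)$out
  x
}

#' Apply the CS-Block measurement operator
#'
#' Maps a normalized image batch to its compressed-domain measurement map.
#' The pre-upsample map has shape `28 x 28 x X` per image (X = [channels_for_sr()]),
#' so its element count relative to the `224 x 224 x 3` input is exactly
#' `X / 192` — the effective sensing rate.  Because the block contains no
#' nonlinearity, the map (pre-upsample) is affine in the input.
#'
#' @param batch An image batch from [load_image_folder()] or
#'   [generate_leaves()], or a bare `224 x 224 x 3 x N` array of normalized
#'   pixels.
#' @param config A [model_config()].
#' @param weights Optional weights: a [build_network()] result whose CS-Block
#'   weights should be used. By default fresh seeded weights are drawn.
#' @param seed Seed for fresh weight initialization (ignored when `weights`
#'   is given).
#' @return A list of class `csb_measurement` with elements `pre` (the
#'   `28 x 28 x X x N` measurement array), `post` (after up-sampling),
#'   `sr` and `effective_sr`.
#' @export
cs_block_forward <- function(batch, config, weights = NULL, seed = 1L) {
  x <- if (is.list(batch)) batch$pixels else batch
  d <- dim(x)
  if (is.null(d) || length(d) != 4L || d[1] != 224L || d[2] != 224L || d[3] != 3L) {
    csb_stop("CS-Block input must be a 224 x 224 x 3 x N array", "csbnet_shape")
  }
  if (config$X < 1L) csb_stop("X must be >= 1", "csbnet_bad_config")
  layers <- if (!is.null(weights)) {
    stopifnot(inherits(weights, "csbnet_model"))
    weights$layers[1:5]
  } else {
    with_seed(derive_seed(seed, "init"), lapply(cs_block_layers(config), init_layer))
  }
  pre <- run_layers(layers[1:4], x)
  post <- layer_forward(layers[[5]], pre)$out
  structure(
    list(pre = pre, post = post, sr = config$sr, effective_sr = effective_sr(config)),
    class = "csb_measurement"
  )
}

#' @export
print.csb_measurement <- function(x, ...) {
  dp <- dim(x$pre)
  cat(sprintf("<measurement map> %d x %d x %d (pre-upsample), effective SR %.4f\n",
              dp[1], dp[2], dp[3], x$effective_sr))
  invisible(x)
}

#' Trainable parameter count of the CS-Block
#'
#' Closed-form accounting over the four convolutions, biases included:
#' `(3*3*3 + 1)*64 + (3*3*64 + 1)*64 * 2 + (64 + 1)*X = 75,648 + 65*X` at the
#' default hidden widths.  The up-sampling stage adds no parameters.
#'
#' @param config A [model_config()].
#' @return Integer parameter count.
#' @export
cs_block_param_count <- function(config) {
  w <- config$cs_widths
  sum(
    (3L * 3L * 3L + 1L) * w[1],
    (3L * 3L * w[1] + 1L) * w[2],
    (3L * 3L * w[2] + 1L) * w[3],
    (w[3] + 1L) * config$X
  )
}
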