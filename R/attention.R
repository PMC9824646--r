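# User-facing attention stages.  Each mechanism maps a feature map
# (H, W, C, N) to a reweighted map of identical shape; all gate values lie
# strictly in (0, 1) because they come out of a sigmoid.

#' Attention specification
#'
#' @param kind One of `"se"`, `"eca"`, `"cbam"`.
#' @param channels Channel count C of the feature map to attend over.
#' @param se_reduction Bottleneck reduction r (SE and the CBAM channel gate);
#'   must divide C.
#' @param eca_gamma,eca_b Adaptive kernel-size rule integers (see
#'   [eca_kernel_size()]).
#' @param cbam_spatial_kernel Spatial-gate kernel size (odd).
#' @return A `csb_attention_spec` list.
#' @export
attention_spec <- function(kind = c("se", "eca", "cbam"),
                           channels,
                           se_reduction = 16L,
                           eca_gamma = 2L,
                           eca_b = 1L,
                           cbam_spatial_kernel = 3L) {
  kind <- match.arg(kind)
  channels <- assert_count(channels, "channels")
  se_reduction <- assert_count(se_reduction, "se_reduction")
  if (kind %in% c("se", "cbam") && channels %% se_reduction != 0L) {
    csb_stop("`channels` must be divisible by `se_reduction`", "csbnet_bad_config")
  }
  if (cbam_spatial_kernel %% 2L == 0L) {
    csb_stop("`cbam_spatial_kernel` must be odd", "csbnet_bad_config")
  }
  structure(list(kind = kind, channels = channels, se_reduction = se_reduction,
                 eca_gamma = as.integer(eca_gamma), eca_b = as.integer(eca_b),
                 cbam_spatial_kernel = as.integer(cbam_spatial_kernel)),
            class = "csb_attention_spec")
}

spec_to_layer <- function(spec) {
  switch(spec$kind,
    se = layer_se("se", spec$channels, spec$se_reduction),
    eca = layer_eca("eca", spec$channels, spec$eca_gamma, spec$eca_b),
    cbam = layer_cbam("cbam", spec$channels, spec$se_reduction, spec$cbam_spatial_kernel)
  )
}

check_feature_map <- function(x, spec) {
  d <- dim(x)
  if (is.null(d) || length(d) != 4L) {
    csb_stop("feature map must be a 4-d array (H, W, C, N)", "csbnet_shape")
  }
  if (d[3] != spec$channels) {
    csb_stop(sprintf("feature map has %d channels, spec expects %d", d[3], spec$channels),
             "csbnet_shape")
  }
  invisible(d)
}

attn_apply <- function(kind, x, spec, weights, seed) {
  check_feature_map(x, spec)
  layer <- if (!is.null(weights)) {
    l <- spec_to_layer(spec); l$params <- weights; l
  } else {
    with_seed(derive_seed(seed, "init"), init_layer(spec_to_layer(spec)))
  }
  layer_forward(layer, x)$out
}

#' Squeeze-and-excitation channel attention
#'
#' Squeeze: global average pooling compresses each HxW channel plane to one
#' number.  Excitation: a biased bottleneck `C -> C/r -> C` two-layer gate
#' (ReLU then sigmoid) produces per-channel weights in (0, 1) that rescale
#' the input channel-wise.  Output shape equals input shape.
#'
#' @param feature_map A `(H, W, C, N)` array.
#' @param spec An [attention_spec()] with matching `channels`.
#' @param weights Optional named list of stage weights (`W1`, `b1`, `W2`,
#'   `b2`); fresh seeded weights by default.
#' @param seed Seed for fresh weights.
#' @return The reweighted feature map, same shape as the input.
#' @export
se_forward <- function(feature_map, spec, weights = NULL, seed = 1L) {
  attn_apply("se", feature_map, spec, weights, seed)
}

#' Efficient channel attention
#'
#' Global average pooling gives a length-C channel descriptor; a single
#' shared (bias-free) 1-D convolution of adaptive kernel size
#' [eca_kernel_size()] followed by a sigmoid yields per-channel weights.
#' Parameter count is exactly `k`.
#'
#' @inheritParams se_forward
#' @export
eca_forward <- function(feature_map, spec, weights = NULL, seed = 1L) {
  attn_apply("eca", feature_map, spec, weights, seed)
}

#' Convolutional block attention (channel then spatial)
#'
#' Channel stage: global max- and average-pooled descriptors pass through a
#' shared biased two-layer MLP, are summed, and gated with a sigmoid.
#' Spatial stage: channel-wise mean and max maps are stacked to 2 channels
#' and convolved (3x3 by default) down to a single-channel sigmoid gate.
#'
#' @inheritParams se_forward
#' @export
cbam_forward <- function(feature_map, spec, weights = NULL, seed = 1L) {
  attn_apply("cbam", feature_map, spec, weights, seed)
}

#' Trainable parameter count of an attention stage
#'
#' SE: `(C * C/r + C/r) + (C/r * C + C)` (both dense layers biased).
#' ECA: `k` (one shared 1-D kernel, no bias).
#' CBAM: the SE-style shared MLP (counted once) plus the spatial convolution
#' `(k^2 * 2 + 1)`.
#'
#' @param spec An [attention_spec()].
#' @return Integer parameter count.
#' @export
attention_param_count <- function(spec) {
  C <- spec$channels
  as.integer(switch(spec$kind,
    se = {
      Cr <- C %/% spec$se_reduction
      (C * Cr + Cr) + (Cr * C + C)
    },
    eca = eca_kernel_size(C, spec$eca_gamma, spec$eca_b),
    cbam = {
      Cr <- C %/% spec$se_reduction
      (C * Cr + Cr) + (Cr * C + C) + (spec$cbam_spatial_kernel^2 * 2L + 1L)
    }
  ))
}
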