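#' Sensing rate
#'
#' The sensing rate SR is the ratio of sampled data volume to original data
#' volume. In CSBNet it determines the channel width of the learned
#' measurement operator: the CS-Block projects to `X = 192 * SR` channels on a
#' 28 x 28 grid, so a 224 x 224 x 3 image (150,528 values) is measured by
#' `28 * 28 * X` values, an element-count ratio of exactly `X / 192`.
#'
#' @param value A single number in (0, 1].
#' @return A `csb_sensing_rate` object (a validated scalar).
#' @examples
#' sensing_rate(0.5)
#' channels_for_sr(sensing_rate(0.7))
#' @export
sensing_rate <- function(value) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      value <= 0 || value > 1) {
    csb_stop("sensing rate must be a single number in (0, 1]",
             "csbnet_invalid_sensing_rate")
  }
  structure(as.numeric(value), class = "csb_sensing_rate")
}

#' @export
print.csb_sensing_rate <- function(x, ...) {
  cat(sprintf("<sensing rate> nominal %.4g, X = %d channels, effective %.4f\n",
              unclass(x), channels_for_sr(x), channels_for_sr(x) / 192))
  invisible(x)
}

#' Measurement channel count for a sensing rate
#'
#' Computes `X = 192 * SR`, rounded half-up to an integer channel count.
#' Because X must be an integer, the effective sensing rate `X / 192` can
#' differ from the nominal SR by up to `0.5 / 192`; see [effective_sr()].
#'
#' @param sr A [sensing_rate()] or a number in (0, 1].
#' @return A positive integer channel count.
#' @export
channels_for_sr <- function(sr) {
  sr <- if (inherits(sr, "csb_sensing_rate")) unclass(sr) else unclass(sensing_rate(sr))
  max(1L, round_half_up(192 * sr))
}

#' Effective sensing rate of a model configuration
#'
#' The realized element-count ratio of the pre-upsample measurement map to the
#' input image: `(28 * 28 * X) / (224 * 224 * 3) = X / 192`. Reported
#' alongside the nominal SR because channel rounding makes the two differ for
#' most rates (e.g. nominal 0.7 gives X = 134 and effective 134/192 = 0.6979).
#'
#' @param config A [model_config()], [sensing_rate()], or number in (0, 1].
#' @return A single number in (0, 1].
#' @export
effective_sr <- function(config) {
  x <- if (inherits(config, "csb_model_config")) config$X else channels_for_sr(config)
  x / 192
}

#' Model configuration
#'
#' Fully determines the CSBNet architecture and therefore its trainable
#' parameter count. Defaults follow the published design: CS-Block hidden
#' widths 64/64/64, a 7x7 stride-4 first feature convolution with 48 filters,
#' fully connected input dimensions 512/1024/2048, 50% dropout, and a
#' squeeze-and-excitation stage with reduction 16 on the 128-channel final
#' feature map. The interior feature widths c2/c3/c4 default to
#' (187, 626, 249), the configuration recovered by [reconstruct_widths()]
#' from the published parameter totals (closest of the exact solutions to
#' AlexNet's 192/384/256).
#'
#' @param sr Sensing rate in (0, 1] (see [sensing_rate()]).
#' @param num_classes Number of classes K (>= 2).
#' @param cs_widths Hidden channel widths of the three 3x3 stride-2
#'   measurement convolutions.
#' @param feat_widths Widths (c2, c3, c4, c5) of feature convolutions 2-5;
#'   c5 must stay 128 so the flattened feature dimension is 512.
#' @param first_feat_filters Filters of the 7x7 stride-4 first feature
#'   convolution.
#' @param fc_dims Input dimensions of the three fully connected layers.
#' @param attention One of `"se"`, `"eca"`, `"cbam"`, `"none"`.
#' @param se_reduction Bottleneck reduction r of the SE (and CBAM channel)
#'   gate; must divide the attended channel count.
#' @param dropout_p Dropout probability in the classifier.
#' @param upsample_factor Nearest-neighbour up-sampling factor after the
#'   measurement projection.
#' @param eca_gamma,eca_b Integers of the adaptive ECA kernel-size rule
#'   `k = nearest odd to (log2(C) + eca_b) / eca_gamma`, floored at 3.
#' @param cbam_spatial_kernel Spatial-gate convolution kernel size (odd).
#' @return A `csb_model_config` list.
#' @examples
#' cfg <- model_config(sr = 0.7, num_classes = 4)
#' cfg$X
#' effective_sr(cfg)
#' @export
model_config <- function(sr = 0.5,
                         num_classes = 4,
                         cs_widths = c(64L, 64L, 64L),
                         feat_widths = c(187L, 626L, 249L, 128L),
                         first_feat_filters = 48L,
                         fc_dims = c(512L, 1024L, 2048L),
                         attention = c("se", "eca", "cbam", "none"),
                         se_reduction = 16L,
                         dropout_p = 0.5,
                         upsample_factor = 2L,
                         eca_gamma = 2L,
                         eca_b = 1L,
                         cbam_spatial_kernel = 3L) {
  sr <- sensing_rate(if (inherits(sr, "csb_sensing_rate")) unclass(sr) else sr)
  attention <- match.arg(attention)
  if (length(cs_widths) != 3L) csb_stop("`cs_widths` must have length 3", "csbnet_bad_config")
  if (length(feat_widths) != 4L) csb_stop("`feat_widths` must have length 4", "csbnet_bad_config")
  if (length(fc_dims) != 3L) csb_stop("`fc_dims` must have length 3", "csbnet_bad_config")
  cs_widths <- vapply(seq_along(cs_widths), function(i)
    assert_count(cs_widths[i], "cs_widths"), integer(1))
  feat_widths <- vapply(seq_along(feat_widths), function(i)
    assert_count(feat_widths[i], "feat_widths"), integer(1))
  fc_dims <- vapply(seq_along(fc_dims), function(i)
    assert_count(fc_dims[i], "fc_dims"), integer(1))
  num_classes <- assert_count(num_classes, "num_classes", min = 2L)
  first_feat_filters <- assert_count(first_feat_filters, "first_feat_filters")
  se_reduction <- assert_count(se_reduction, "se_reduction")
  upsample_factor <- assert_count(upsample_factor, "upsample_factor")
  eca_gamma <- assert_count(eca_gamma, "eca_gamma")
  eca_b <- assert_count(eca_b, "eca_b", min = 0L)
  cbam_spatial_kernel <- assert_count(cbam_spatial_kernel, "cbam_spatial_kernel")
  if (cbam_spatial_kernel %% 2L == 0L) {
    csb_stop("`cbam_spatial_kernel` must be odd", "csbnet_bad_config")
  }
  dropout_p <- assert_fraction(dropout_p, "dropout_p")
  # Flatten-dimension consistency: the adaptive pool emits 2 x 2 spatial cells.
  if (fc_dims[1] != feat_widths[4] * 4L) {
    csb_stop("fc_dims[1] must equal feat_widths[4] * 2 * 2 (flatten dimension)",
             "csbnet_bad_config")
  }
  if (attention %in% c("se", "cbam") && feat_widths[4] %% se_reduction != 0L) {
    csb_stop("attended channel count must be divisible by `se_reduction`",
             "csbnet_bad_config")
  }
  structure(
    list(
      sr = sr,
      X = channels_for_sr(sr),
      num_classes = num_classes,
      cs_widths = cs_widths,
      feat_widths = feat_widths,
      first_feat_filters = first_feat_filters,
      fc_dims = fc_dims,
      attention = attention,
      se_reduction = se_reduction,
      dropout_p = dropout_p,
      upsample_factor = upsample_factor,
      eca_gamma = eca_gamma,
      eca_b = eca_b,
      cbam_spatial_kernel = cbam_spatial_kernel
    ),
    class = "csb_model_config"
  )
}

#' @export
print.csb_model_config <- function(x, ...) {
  cat("<csbnet model config>\n")
  cat(sprintf("  sensing rate: %.4g (X = %d, effective %.4f)\n",
              unclass(x$sr), x$X, effective_sr(x)))
  cat(sprintf("  classes: %d | attention: %s | dropout: %.2f\n",
              x$num_classes, x$attention, x$dropout_p))
  cat(sprintf("  cs widths: %s -> X | feature widths: 48,%s\n",
              paste(x$cs_widths, collapse = ","),
              paste(x$feat_widths, collapse = ",")))
  cat(sprintf("  classifier: %s -> %d\n",
              paste(x$fc_dims, collapse = " -> "), x$num_classes))
  invisible(x)
}

#' Training configuration
#'
#' @param learning_rate Adam step size; the published setting is 1e-4.
#' @param epochs Number of passes over the training set.
#' @param batch_size Minibatch size.
#' @param seed Integer seed driving shuffling, augmentation, weight
#'   initialization and dropout (split internally into per-purpose streams).
#' @param optimizer Only `"adam"` is supported.
#' @param clip_norm Global gradient-norm ceiling; gradients are rescaled when
#'   their joint L2 norm exceeds it. Guards the ReLU stack against
#'   dying-unit collapse from unstable early updates. `Inf` disables.
#' @return A `csb_train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4,
                         epochs = 5,
                         batch_size = 8,
                         seed = 1L,
                         optimizer = "adam",
                         clip_norm = 1) {
  if (!identical(optimizer, "adam")) {
    csb_stop("`optimizer` must be \"adam\"", "csbnet_bad_config")
  }
  # 0 is allowed as the degenerate no-update optimizer (useful in tests)
  if (!is.numeric(learning_rate) || length(learning_rate) != 1L || learning_rate < 0) {
    csb_stop("`learning_rate` must be a single non-negative number", "csbnet_bad_config")
  }
  if (!is.numeric(clip_norm) || length(clip_norm) != 1L || clip_norm <= 0) {
    csb_stop("`clip_norm` must be a single positive number (Inf to disable)",
             "csbnet_bad_config")
  }
  structure(
    list(
      learning_rate = as.numeric(learning_rate),
      epochs = assert_count(epochs, "epochs"),
      batch_size = assert_count(batch_size, "batch_size"),
      seed = assert_count(seed, "seed", min = 0L),
      optimizer = "adam",
      clip_norm = as.numeric(clip_norm)
    ),
    class = "csb_train_config"
  )
}

#' @export
print.csb_train_config <- function(x, ...) {
  cat(sprintf("<csbnet train config> adam, lr %.2g, %d epochs, batch %d, seed %d\n",
              x$learning_rate, x$epochs, x$batch_size, x$seed))
  invisible(x)
}

# configuration file i/o -------------------------------------------------------

config_field_names <- list(
  model = c("sr", "num_classes", "cs_widths", "feat_widths",
            "first_feat_filters", "fc_dims", "attention", "se_reduction",
            "dropout_p", "upsample_factor", "eca_gamma", "eca_b",
            "cbam_spatial_kernel"),
  train = c("learning_rate", "epochs", "batch_size", "seed", "optimizer", "clip_norm")
)

#' Read a configuration file
#'
#' Reads a YAML (or JSON, which YAML subsumes) file with optional top-level
#' `model:` and `train:` sections whose keys match the [model_config()] and
#' [train_config()] argument names exactly. Unknown keys are an error, so a
#' typo cannot silently fall back to a default.
#'
#' @param path Path to the configuration file.
#' @return A list with elements `model` (`csb_model_config`) and `train`
#'   (`csb_train_config`).
#' @seealso [write_config()]
#' @export
read_config <- function(path) {
  if (!file.exists(path)) csb_stop(paste0("config file not found: ", path), "csbnet_io")
  raw <- yaml::read_yaml(path)
  bad_top <- setdiff(names(raw), c("model", "train"))
  if (length(bad_top)) {
    csb_stop(paste0("unknown top-level config keys: ", paste(bad_top, collapse = ", ")),
             "csbnet_bad_config")
  }
  check_keys <- function(section, allowed) {
    bad <- setdiff(names(section), allowed)
    if (length(bad)) {
      csb_stop(paste0("unknown config keys: ", paste(bad, collapse = ", ")),
               "csbnet_bad_config")
    }
    section
  }
  model <- do.call(model_config, check_keys(raw$model %||% list(), config_field_names$model))
  train <- do.call(train_config, check_keys(raw$train %||% list(), config_field_names$train))
  list(model = model, train = train)
}

#' Write a configuration file
#'
#' Serializes configurations to YAML such that [read_config()] round-trips
#' them exactly.
#'
#' @param model A [model_config()].
#' @param train A [train_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(model, train = train_config(), path) {
  stopifnot(inherits(model, "csb_model_config"), inherits(train, "csb_train_config"))
  m <- unclass(model)
  m$sr <- unclass(m$sr)
  m$X <- NULL  # derived
  yaml::write_yaml(list(model = m, train = unclass(train)), path)
  invisible(path)
}
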