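# ggplot2 visualizations for the result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_tile
#'   geom_text labs scale_fill_gradient theme_minimal facet_wrap
#'   scale_x_continuous
NULL

#' Plot a training run
#'
#' Loss and validation-accuracy curves over epochs.
#'
#' @param object A `csbnet_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot csbnet_fit
#' @export
autoplot.csbnet_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, -"epoch",
                            names_to = "metric", values_to = "value")
  df <- df[!is.na(df$value), ]
  ggplot(df, aes(x = .data$epoch, y = .data$value)) +
    geom_line() + geom_point() +
    facet_wrap(~metric, scales = "free_y") +
    scale_x_continuous(breaks = unique(df$epoch)) +
    labs(x = "epoch", y = NULL, title = "Training history") +
    theme_minimal()
}

#' Plot a sensing-rate sweep
#'
#' Accuracy against sensing rate; the expected trend is non-decreasing.
#'
#' @param object A [sr_sweep()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot csb_sweep
#' @export
autoplot.csb_sweep <- function(object, ...) {
  ggplot(object, aes(x = .data$sr, y = .data$accuracy)) +
    geom_line() + geom_point() +
    labs(x = "sensing rate (nominal)", y = "validation accuracy",
         title = "Accuracy vs sensing rate") +
    theme_minimal()
}

#' Plot a confusion matrix
#'
#' @param object A [confusion()] matrix.
#' @param ... Unused.
#' @return A ggplot heat map with counts annotated.
#' @method autoplot csb_confusion
#' @export
autoplot.csb_confusion <- function(object, ...) {
  cn <- attr(object, "class_names")
  df <- expand.grid(true = cn, predicted = cn, stringsAsFactors = FALSE)
  df$count <- as.vector(unclass(object))
  ggplot(df, aes(x = .data$predicted, y = .data$true, fill = .data$count)) +
    geom_tile() +
    geom_text(aes(label = .data$count)) +
    scale_fill_gradient(low = "white", high = "steelblue") +
    labs(title = "Confusion matrix") +
    theme_minimal()
}

#' @importFrom rlang .data
NULL
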