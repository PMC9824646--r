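# Confusion-matrix construction and the derived evaluation metrics.
# Rows are true classes, columns predicted classes; every metric is computed
# from these counts alone.

#' Build a confusion matrix
#'
#' @param true_labels,predicted_labels Integer vectors with values in
#'   `[0, K)`, equal length.
#' @param K Number of classes.
#' @param class_names Optional length-K character vector.
#' @return A `csb_confusion` object: a K x K integer matrix
#'   (`counts[i, j]` = samples with true class i-1 predicted as j-1) with a
#'   `class_names` attribute.
#' @examples
#' cm <- confusion(c(0, 0, 1, 2), c(0, 1, 1, 2), K = 3)
#' score(cm)
#' @export
confusion <- function(true_labels, predicted_labels, K, class_names = NULL) {
  if (length(true_labels) != length(predicted_labels)) {
    csb_stop("label vectors must have equal length", "csbnet_bad_input")
  }
  K <- assert_count(K, "K")
  if (length(true_labels) == 0L) csb_stop("no samples", "csbnet_bad_input")
  if (any(true_labels < 0 | true_labels >= K | predicted_labels < 0 | predicted_labels >= K)) {
    csb_stop("labels must lie in [0, K)", "csbnet_bad_input")
  }
  if (is.null(class_names)) class_names <- paste0("class_", seq_len(K) - 1L)
  counts <- table(factor(true_labels, levels = 0:(K - 1L)),
                  factor(predicted_labels, levels = 0:(K - 1L)))
  m <- matrix(as.integer(counts), K, K,
              dimnames = list(true = class_names, predicted = class_names))
  structure(m, class = c("csb_confusion", "matrix"), class_names = class_names)
}

#' Score a confusion matrix
#'
#' Computes accuracy (trace / total) and one-vs-rest precision, recall and
#' F1 per class, plus their unweighted (macro) means.  For class k the
#' one-vs-rest counts are `TP = counts[k,k]`, `FP = colsum - TP`,
#' `FN = rowsum - TP`; precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, and
#' `F1 = 2PR/(P+R)`.  A metric whose denominator is zero (e.g. a class never
#' predicted) is reported as 0 with a warning.
#'
#' @param cm A [confusion()] matrix (or any square count matrix).
#' @return A `csb_metrics` list: `accuracy`, `per_class` (tibble with class,
#'   precision, recall, f1, support), and `macro_precision`, `macro_recall`,
#'   `macro_f1`.
#' @export
score <- function(cm) {
  m <- unclass(cm)
  if (!is.matrix(m) || nrow(m) != ncol(m)) csb_stop("`cm` must be square", "csbnet_bad_input")
  total <- sum(m)
  if (total <= 0) csb_stop("empty confusion matrix", "csbnet_bad_input")
  K <- nrow(m)
  cn <- attr(cm, "class_names") %||% rownames(m) %||% paste0("class_", seq_len(K) - 1L)
  tp <- unname(diag(m))
  fp <- unname(colSums(m)) - tp
  fn <- unname(rowSums(m)) - tp
  safe_div <- function(num, den, what) {
    bad <- den == 0
    if (any(bad)) {
      warn(sprintf("%s undefined for class(es) %s (zero denominator); reported as 0",
                   what, paste(cn[bad], collapse = ", ")))
    }
    ifelse(bad, 0, num / den)
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- safe_div(2 * precision * recall, precision + recall, "F1")
  structure(
    list(
      accuracy = sum(tp) / total,
      per_class = tibble::tibble(class = cn, precision = precision,
                                 recall = recall, f1 = f1,
                                 support = as.integer(rowSums(m))),
      macro_precision = mean(precision),
      macro_recall = mean(recall),
      macro_f1 = mean(f1),
      n = as.integer(total)
    ),
    class = "csb_metrics"
  )
}

#' @export
print.csb_metrics <- function(x, ...) {
  cat(sprintf("<metrics> accuracy %.4f on %d samples\n", x$accuracy, x$n))
  cat(sprintf("  macro P %.4f | macro R %.4f | macro F1 %.4f\n",
              x$macro_precision, x$macro_recall, x$macro_f1))
  print(x$per_class)
  invisible(x)
}

#' Tidy a metrics report
#'
#' @param x A `csb_metrics` object.
#' @param ... Unused.
#' @return A tibble with one row per class plus a `macro` row
#'   (columns: class, precision, recall, f1, support).
#' @method tidy csb_metrics
#' @export
tidy.csb_metrics <- function(x, ...) {
  dplyr::bind_rows(
    x$per_class,
    tibble::tibble(class = "macro", precision = x$macro_precision,
                   recall = x$macro_recall, f1 = x$macro_f1,
                   support = x$n)
  )
}

#' @rdname tidy.csb_metrics
#' @return `glance()` returns a one-row tibble with accuracy and macro
#'   averages.
#' @method glance csb_metrics
#' @export
glance.csb_metrics <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, macro_precision = x$macro_precision,
                 macro_recall = x$macro_recall, macro_f1 = x$macro_f1, n = x$n)
}

#' Write a metrics report to CSV or JSON
#'
#' CSV holds one row per class plus the macro row; JSON additionally records
#' overall accuracy.
#'
#' @param metrics A [score()] result.
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  stopifnot(inherits(metrics, "csb_metrics"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(accuracy = metrics$accuracy,
           macro = list(precision = metrics$macro_precision,
                        recall = metrics$macro_recall, f1 = metrics$macro_f1),
           per_class = as.data.frame(metrics$per_class), n = metrics$n),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    write.csv(as.data.frame(tidy.csb_metrics(metrics)), path, row.names = FALSE)
  }
  invisible(path)
}
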