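# Cross-entropy/Adam training with the sensing-rate sweep harness.

#' Cross-entropy between two distributions
#'
#' `H(p, q) = -sum p(x) log q(x)` with the natural logarithm, where p is the
#' desired (true) distribution and q the predicted one.  Smaller is better;
#' by Gibbs' inequality `H(p, q) >= H(p, p)` with equality iff q = p.  A
#' floor of `eps` inside the log guards the undefined case q = 0 where
#' p > 0.
#'
#' @param p,q Non-negative numeric vectors of equal length summing to 1.
#' @param eps Floor inside the logarithm.
#' @return A single non-negative number.
#' @examples
#' cross_entropy(c(1, 0, 0, 0), c(1, 0, 0, 0))      # 0
#' cross_entropy(c(1, 0, 0, 0), rep(0.25, 4))       # log(4)
#' @export
cross_entropy <- function(p, q, eps = 1e-12) {
  if (length(p) != length(q)) csb_stop("p and q must have equal length", "csbnet_bad_input")
  if (any(p < 0) || any(q < 0)) csb_stop("distributions must be non-negative", "csbnet_bad_input")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6) {
    csb_stop("p and q must each sum to 1", "csbnet_bad_input")
  }
  -sum(p * log(pmax(q, eps)))
}

# Adam state mirrors the nested grads structure (one slot per layer/param).
adam_init <- function(net) {
  lapply(net$layers, function(l) {
    lapply(l$params, function(p) {
      if (is.null(p)) NULL else list(m = p * 0, v = p * 0)
    })
  })
}

adam_step <- function(net, grads, state, t, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    if (!length(g)) next
    for (nm in names(g)) {
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[nm]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[nm]]^2
      net$layers[[i]]$params[[nm]] <- net$layers[[i]]$params[[nm]] -
        lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
      state[[i]][[nm]] <- st
    }
  }
  list(net = net, state = state)
}

# rescale all gradients jointly so their global L2 norm is at most `max_norm`
clip_global_norm <- function(grads, max_norm) {
  if (!is.finite(max_norm)) return(grads)
  total <- sum(vapply(grads, function(g)
    sum(vapply(g, function(p) sum(p^2), numeric(1))), numeric(1)))
  gn <- sqrt(total)
  if (gn <= max_norm) return(grads)
  scale <- max_norm / gn
  lapply(grads, function(g) lapply(g, function(p) p * scale))
}

# mean cross-entropy over a scores matrix (K x N) and 0-based labels,
# together with the score gradient (softmax - onehot) / N
softmax_xent <- function(scores, labels, eps = 1e-12) {
  N <- ncol(scores)
  probs <- softmax_cols(scores)
  picked <- probs[cbind(labels + 1L, seq_len(N))]
  loss <- -mean(log(pmax(picked, eps)))
  donehot <- probs
  donehot[cbind(labels + 1L, seq_len(N))] <- picked - 1
  list(loss = loss, dscores = donehot / N, probs = probs)
}

evaluate_batch <- function(net, batch) {
  scores <- net_forward(net, batch$pixels)$scores
  pred <- max.col(t(scores), ties.method = "first") - 1L
  cm <- confusion(batch$labels, pred, net$config$num_classes, batch$class_names)
  score(cm)
}

#' Train a CSBNet network
#'
#' Minibatch Adam (beta1 = 0.9, beta2 = 0.999) on mean cross-entropy, with
#' seeded flip/brightness augmentation applied to each training minibatch.
#' One integer seed drives shuffling, augmentation and dropout, so the same
#' seed on the same data reproduces the run exactly.
#'
#' @param net A [build_network()] model.
#' @param train_batch,val_batch Image batches; validation may be `NULL`.
#' @param tc A [train_config()].
#' @param augment_train Apply augmentation to training minibatches.
#' @param verbose Print one line per epoch.
#' @return A `csbnet_fit`: the trained `network`, a `history` tibble
#'   (epoch, train_loss, val_accuracy), and the final validation `metrics`.
#' @export
train <- function(net, train_batch, val_batch = NULL, tc = train_config(),
                  augment_train = TRUE, verbose = FALSE) {
  stopifnot(inherits(net, "csbnet_model"), inherits(tc, "csb_train_config"))
  n <- batch_size(train_batch)
  if (n == 0L) csb_stop("empty training set", "csbnet_bad_input")
  if (max(train_batch$labels) >= net$config$num_classes) {
    csb_stop("label classes exceed network output width", "csbnet_bad_input")
  }
  state <- adam_init(net)
  t <- 0L
  history <- vector("list", tc$epochs)
  with_seed(derive_seed(tc$seed, "shuffle"), {
    for (epoch in seq_len(tc$epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1L, n, by = tc$batch_size)) {
        idx <- ord[start:min(start + tc$batch_size - 1L, n)]
        mb <- batch_subset(train_batch, idx)
        if (augment_train) mb <- augment(mb, seed = NULL)
        fw <- net_forward(net, mb$pixels, training = TRUE, with_caches = TRUE)
        sx <- softmax_xent(fw$scores, mb$labels)
        if (!is.finite(sx$loss)) {
          csb_stop(sprintf("non-finite loss at epoch %d (diverged?)", epoch),
                   "csbnet_diverged")
        }
        losses <- c(losses, sx$loss)
        grads <- net_backward(net, fw$caches, sx$dscores)
        grads <- clip_global_norm(grads, tc$clip_norm)
        t <- t + 1L
        upd <- adam_step(net, grads, state, t, tc$learning_rate)
        net <- upd$net; state <- upd$state
      }
      val_acc <- if (!is.null(val_batch)) evaluate_batch(net, val_batch)$accuracy else NA_real_
      history[[epoch]] <- tibble::tibble(epoch = epoch,
                                         train_loss = mean(losses),
                                         val_accuracy = val_acc)
      if (verbose) {
        cat(sprintf("epoch %d | loss %.4f | val acc %s\n", epoch, mean(losses),
                    ifelse(is.na(val_acc), "-", sprintf("%.4f", val_acc))))
      }
    }
  })
  metrics <- if (!is.null(val_batch)) evaluate_batch(net, val_batch) else NULL
  structure(list(network = net, history = dplyr::bind_rows(history),
                 metrics = metrics, tc = tc),
            class = "csbnet_fit")
}

#' @export
print.csbnet_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf("<csbnet fit> %d epochs | final loss %.4f | val acc %s\n",
              nrow(x$history), last$train_loss,
              ifelse(is.na(last$val_accuracy), "-", sprintf("%.4f", last$val_accuracy))))
  invisible(x)
}

#' Tidy / summarize a training run
#'
#' @param x A `csbnet_fit`.
#' @param ... Unused.
#' @return `tidy()` returns the per-epoch history tibble; `glance()` a
#'   one-row summary (final loss, final/best validation accuracy, epochs).
#' @method tidy csbnet_fit
#' @export
tidy.csbnet_fit <- function(x, ...) x$history

#' @rdname tidy.csbnet_fit
#' @method glance csbnet_fit
#' @export
glance.csbnet_fit <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$history),
    final_train_loss = x$history$train_loss[nrow(x$history)],
    final_val_accuracy = x$history$val_accuracy[nrow(x$history)],
    best_val_accuracy = suppressWarnings(max(x$history$val_accuracy, na.rm = TRUE)),
    macro_f1 = if (!is.null(x$metrics)) x$metrics$macro_f1 else NA_real_
  )
}

#' Write a training history to CSV
#'
#' @param fit A `csbnet_fit`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_history <- function(fit, path) {
  stopifnot(inherits(fit, "csbnet_fit"))
  write.csv(as.data.frame(fit$history), path, row.names = FALSE)
  invisible(path)
}

#' Sensing-rate sweep
#'
#' Trains one fresh network per sensing rate (same seed policy and data for
#' each) and evaluates on held-out data.  The classification accuracy is
#' expected to trend upward with SR — more measurement channels retain more
#' of the image — and the sweep table is the desk-scale analogue of that
#' comparison.  The published experiments use the grid
#' `0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7`.
#'
#' @param srs Numeric vector of sensing rates.
#' @param train_batch,val_batch Image batches.
#' @param tc A [train_config()].
#' @param config Base [model_config()]; its `sr` is replaced per sweep point.
#' @param augment_train Apply augmentation to training minibatches (passed to
#'   [train()]).
#' @param verbose Print per-epoch progress.
#' @return A tibble of class `csb_sweep`, sorted by SR: sr, effective_sr, X,
#'   accuracy, macro_precision, macro_recall, macro_f1.
#' @export
sr_sweep <- function(srs = c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7),
                     train_batch, val_batch, tc = train_config(),
                     config = model_config(), augment_train = TRUE,
                     verbose = FALSE) {
  rows <- lapply(sort(srs), function(s) {
    cfg <- model_config(
      sr = s, num_classes = config$num_classes, cs_widths = config$cs_widths,
      feat_widths = config$feat_widths, first_feat_filters = config$first_feat_filters,
      fc_dims = config$fc_dims, attention = config$attention,
      se_reduction = config$se_reduction, dropout_p = config$dropout_p,
      upsample_factor = config$upsample_factor, eca_gamma = config$eca_gamma,
      eca_b = config$eca_b, cbam_spatial_kernel = config$cbam_spatial_kernel)
    net <- build_network(cfg, seed = tc$seed)
    fit <- train(net, train_batch, val_batch, tc, augment_train = augment_train,
                 verbose = verbose)
    m <- fit$metrics
    tibble::tibble(sr = s, effective_sr = effective_sr(cfg), X = cfg$X,
                   accuracy = m$accuracy, macro_precision = m$macro_precision,
                   macro_recall = m$macro_recall, macro_f1 = m$macro_f1)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("csb_sweep", class(out))
  out
}

#' Rank correlation between SR and accuracy in a sweep
#'
#' Spearman correlation, with the convention that a constant accuracy vector
#' (no variation to rank) counts as 0 — a flat trend, not a missing value.
#'
#' @param sweep A [sr_sweep()] result.
#' @return A number in `[-1, 1]`.
#' @export
sweep_trend <- function(sweep) {
  if (nrow(sweep) < 2L || stats::sd(sweep$accuracy) == 0) return(0)
  cor(sweep$sr, sweep$accuracy, method = "spearman")
}
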