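# Shared test utilities: finite-difference gradients and tiny fixtures.

ns <- asNamespace("csbnet")

# central finite differences of a scalar-valued function
num_grad <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}

max_rel_err <- function(a, b) {
  max(abs(a - b)) / max(1e-8, max(abs(a)), max(abs(b)))
}

reshape_like <- function(v, p) if (is.null(dim(p))) as.numeric(v) else array(v, dim(p))

# analytic-vs-numeric gradient check for one layer (input and every param)
gradcheck_layer <- function(layer, d_in, seed = 42) {
  set.seed(seed)
  layer <- ns$init_layer(layer)
  x <- array(rnorm(prod(d_in)), d_in)
  fw <- ns$layer_forward(layer, x)
  w <- array(rnorm(length(fw$out)), dim(fw$out) %||% length(fw$out))
  loss_x <- function(xv) sum(w * ns$layer_forward(layer, array(xv, d_in))$out)
  bw <- ns$layer_backward(layer, fw$cache, w)
  errs <- c(dx = max_rel_err(num_grad(loss_x, x), bw$dx))
  for (nm in names(layer$params)) {
    p0 <- layer$params[[nm]]
    lp <- function(pv) {
      l2 <- layer
      l2$params[[nm]] <- reshape_like(pv, p0)
      sum(w * ns$layer_forward(l2, x)$out)
    }
    errs[nm] <- max_rel_err(num_grad(lp, p0), bw$grads[[nm]])
  }
  errs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a small normalized image batch with distinguishable per-class content
tiny_batch <- function(n_per_class = 2, seed = 5) {
  generate_leaves(synthetic_spec(n_per_class = n_per_class, seed = seed))$batch
}

# a deliberately asymmetric 3x3 single-image batch for flip oracles
asym_batch <- function() {
  px <- array(0, c(224, 224, 3, 1))
  px[, , , 1] <- seq(-1, 1, length.out = 224 * 224 * 3)
  csbnet:::new_image_batch(px, 0L, "only")
}
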