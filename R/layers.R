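# Minimal tensor/layer engine.
#
# Tensors are numeric arrays with dim (H, W, C, N) — spatial rows, spatial
# columns, channels, batch.  Convolution is im2col + GEMM so the heavy
# arithmetic runs in BLAS; the backward pass scatters gradients back with one
# vectorized add per kernel offset (indices are collision-free for a fixed
# offset).  Everything is double precision, which is what makes the
# finite-difference gradient checks in the test suite meaningful.

sigmoid <- function(x) 1 / (1 + exp(-x))

# layer constructors ----------------------------------------------------------

layer_conv <- function(name, k, stride, pad, c_in, c_out, activation = "linear") {
  list(type = "conv", name = name, k = k, stride = stride, pad = pad,
       c_in = c_in, c_out = c_out, activation = activation,
       params = list(W = NULL, b = NULL))
}

layer_maxpool <- function(name, k = 3L, stride = 2L) {
  list(type = "maxpool", name = name, k = k, stride = stride, params = list())
}

layer_upsample <- function(name, factor = 2L) {
  list(type = "upsample", name = name, factor = factor, params = list())
}

layer_adaptive_avgpool <- function(name, out = 2L) {
  list(type = "adaptpool", name = name, out = out, params = list())
}

layer_flatten <- function(name) list(type = "flatten", name = name, params = list())

layer_dropout <- function(name, p) list(type = "dropout", name = name, p = p, params = list())

layer_fc <- function(name, d_in, d_out, activation = "linear") {
  list(type = "fc", name = name, d_in = d_in, d_out = d_out,
       activation = activation, params = list(W = NULL, b = NULL))
}

layer_se <- function(name, channels, reduction) {
  list(type = "se", name = name, channels = channels, reduction = reduction,
       params = list(W1 = NULL, b1 = NULL, W2 = NULL, b2 = NULL))
}

layer_eca <- function(name, channels, gamma = 2L, b = 1L) {
  list(type = "eca", name = name, channels = channels,
       k = eca_kernel_size(channels, gamma, b), params = list(w = NULL))
}

layer_cbam <- function(name, channels, reduction, spatial_kernel = 3L) {
  list(type = "cbam", name = name, channels = channels, reduction = reduction,
       spatial_kernel = spatial_kernel,
       params = list(W1 = NULL, b1 = NULL, W2 = NULL, b2 = NULL,
                     Wsp = NULL, bsp = NULL))
}

#' Adaptive kernel size of the efficient-channel-attention gate
#'
#' `k` grows logarithmically with the channel count:
#' `k = odd(floor((log2(C) + b) / gamma))` where `odd()` rounds an even value
#' up to the next odd integer, floored at 3 so the 1-D convolution always sees
#' at least one neighbour on each side.
#'
#' @param channels Channel count C.
#' @param gamma,b Integers of the adaptive rule.
#' @return An odd integer >= 3.
#' @export
eca_kernel_size <- function(channels, gamma = 2L, b = 1L) {
  t <- floor((log2(channels) + b) / gamma)
  k <- if (t %% 2 == 1) t else t + 1
  as.integer(max(3, k))
}

# initialization ---------------------------------------------------------------

# He-style scaling for ReLU layers, plain fan-in scaling for linear/gate
# layers; biases start at zero.  Consumes the current RNG stream.
init_layer <- function(layer) {
  gain <- function(act, fan_in) if (identical(act, "relu")) sqrt(2 / fan_in) else sqrt(1 / fan_in)
  switch(layer$type,
    conv = {
      k2c <- layer$k^2 * layer$c_in
      layer$params$W <- matrix(rnorm(k2c * layer$c_out, sd = gain(layer$activation, k2c)),
                               k2c, layer$c_out)
      layer$params$b <- numeric(layer$c_out)
    },
    fc = {
      layer$params$W <- matrix(rnorm(layer$d_out * layer$d_in,
                                     sd = gain(layer$activation, layer$d_in)),
                               layer$d_out, layer$d_in)
      layer$params$b <- numeric(layer$d_out)
    },
    se = {
      C <- layer$channels; Cr <- C %/% layer$reduction
      layer$params$W1 <- matrix(rnorm(Cr * C, sd = sqrt(2 / C)), Cr, C)
      layer$params$b1 <- numeric(Cr)
      layer$params$W2 <- matrix(rnorm(C * Cr, sd = sqrt(1 / Cr)), C, Cr)
      layer$params$b2 <- numeric(C)
    },
    eca = {
      layer$params$w <- rnorm(layer$k, sd = sqrt(1 / layer$k))
    },
    cbam = {
      C <- layer$channels; Cr <- C %/% layer$reduction; ks <- layer$spatial_kernel
      layer$params$W1 <- matrix(rnorm(Cr * C, sd = sqrt(2 / C)), Cr, C)
      layer$params$b1 <- numeric(Cr)
      layer$params$W2 <- matrix(rnorm(C * Cr, sd = sqrt(1 / Cr)), C, Cr)
      layer$params$b2 <- numeric(C)
      layer$params$Wsp <- matrix(rnorm(ks^2 * 2, sd = sqrt(1 / (ks^2 * 2))), ks^2 * 2, 1)
      layer$params$bsp <- 0
    },
    layer
  )
  layer
}

# convolution core -------------------------------------------------------------

conv_out_dim <- function(n, k, stride, pad) (n + 2L * pad - k) %/% stride + 1L

pad_spatial <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3], d[4]))
  xp[(p + 1):(p + d[1]), (p + 1):(p + d[2]), , ] <- x
  xp
}

# im2col index matrix (P x K) into one padded image slice; output positions
# run row-fastest so column P matches the column-major fill of (OH, OW).
# Integer storage keeps the gather/scatter indexing on the fast path.
conv_idx <- function(Hp, Wp, C, k, stride, OH, OW) {
  base <- outer((0:(OH - 1L)) * as.integer(stride) + 1L,
                ((0:(OW - 1L)) * as.integer(stride)) * Hp, "+")
  off0 <- outer(0:(k - 1L), (0:(k - 1L)) * Hp, "+")
  off <- outer(as.vector(off0), (0:(C - 1L)) * (Hp * Wp), "+")
  m <- outer(as.vector(base), as.vector(off), "+")
  storage.mode(m) <- "integer"
  m
}

conv_forward <- function(layer, x, keep_patches = FALSE) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  if (C != layer$c_in) {
    csb_stop(sprintf("conv '%s' expects %d input channels, got %d",
                     layer$name, layer$c_in, C), "csbnet_shape")
  }
  k <- layer$k; s <- layer$stride; p <- layer$pad
  OH <- conv_out_dim(H, k, s, p); OW <- conv_out_dim(W, k, s, p)
  if (OH < 1L || OW < 1L) {
    csb_stop(sprintf("conv '%s': input %dx%d too small for kernel %d stride %d",
                     layer$name, H, W, k, s), "csbnet_shape")
  }
  xp <- pad_spatial(x, p)
  Hp <- H + 2L * p; Wp <- W + 2L * p
  idx <- conv_idx(Hp, Wp, C, k, s, OH, OW)
  P <- OH * OW
  K <- ncol(idx)
  slice <- as.integer(Hp * Wp * C)
  Wm <- layer$params$W; b <- layer$params$b
  out <- array(0, c(OH, OW, layer$c_out, N))
  patches_list <- if (keep_patches) vector("list", N) else NULL
  # index with a plain vector: a K-column integer matrix would be taken as
  # coordinate subscripts whenever K equals the array's dimensionality
  for (n in seq_len(N)) {
    patches <- xp[as.vector(idx) + (n - 1L) * slice]
    dim(patches) <- c(P, K)
    o <- patches %*% Wm
    o <- o + rep(b, each = P)
    out[, , , n] <- o
    if (keep_patches) patches_list[[n]] <- patches
  }
  relu_mask <- NULL
  if (identical(layer$activation, "relu")) {
    relu_mask <- out > 0
    out <- out * relu_mask
  }
  list(out = out,
       cache = list(in_dim = d, OH = OH, OW = OW, relu_mask = relu_mask,
                    idx = idx, slice = slice, patches = patches_list,
                    xp = if (keep_patches) NULL else xp))
}

conv_backward <- function(layer, cache, dout) {
  if (!is.null(cache$relu_mask)) dout <- dout * cache$relu_mask
  d <- cache$in_dim; H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  k <- layer$k; s <- layer$stride; p <- layer$pad
  OH <- cache$OH; OW <- cache$OW; P <- OH * OW
  Hp <- H + 2L * p; Wp <- W + 2L * p
  idx <- cache$idx; slice <- cache$slice
  Wm <- layer$params$W
  K <- nrow(Wm)
  dW <- matrix(0, K, ncol(Wm))
  db <- numeric(ncol(Wm))
  dxpv <- numeric(Hp * Wp * C * N)
  kk2 <- k * k
  colsets <- lapply(seq_len(kk2), function(j) seq(j, by = kk2, length.out = C))
  for (n in seq_len(N)) {
    dOn <- matrix(dout[, , , n], P, ncol(Wm))
    patches <- if (!is.null(cache$patches)) cache$patches[[n]] else {
      pv <- cache$xp[as.vector(idx) + (n - 1L) * slice]; dim(pv) <- c(P, K); pv
    }
    dW <- dW + crossprod(patches, dOn)
    db <- db + colSums(dOn)
    dPn <- tcrossprod(dOn, Wm)                       # P x K
    off_n <- (n - 1L) * slice
    # for a fixed kernel offset the target indices are collision-free
    for (j in seq_len(kk2)) {
      tgt <- as.vector(idx[, colsets[[j]]]) + off_n
      dxpv[tgt] <- dxpv[tgt] + dPn[, colsets[[j]]]
    }
  }
  dxp <- array(dxpv, c(Hp, Wp, C, N))
  dx <- if (p > 0L) dxp[(p + 1):(p + H), (p + 1):(p + W), , , drop = FALSE] else dxp
  list(dx = dx, grads = list(W = dW, b = db))
}

# pooling ----------------------------------------------------------------------

maxpool_forward <- function(layer, x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  k <- layer$k; s <- layer$stride
  OH <- conv_out_dim(H, k, s, 0L); OW <- conv_out_dim(W, k, s, 0L)
  if (OH < 1L || OW < 1L) {
    csb_stop(sprintf("maxpool '%s': input %dx%d too small", layer$name, H, W),
             "csbnet_shape")
  }
  P <- OH * OW; S <- C * N; HW <- H * W
  idx <- conv_idx(H, W, 1L, k, s, OH, OW)            # P x k^2 within one slice
  soff <- rep((0:(S - 1L)) * HW, each = P)
  M <- matrix(0, P * S, k * k)
  xv <- as.vector(x)
  for (j in seq_len(k * k)) M[, j] <- xv[rep(idx[, j], S) + soff]
  amax <- max.col(M, ties.method = "first")
  out <- array(M[cbind(seq_len(P * S), amax)], c(OH, OW, C, N))
  list(out = out, cache = list(in_dim = d, OH = OH, OW = OW, idx = idx,
                               soff = soff, amax = amax))
}

maxpool_backward <- function(layer, cache, dout) {
  d <- cache$in_dim
  P <- cache$OH * cache$OW; S <- d[3] * d[4]
  dxv <- numeric(prod(d))
  dov <- as.vector(dout)
  full_j <- function(j) rep(cache$idx[, j], S) + cache$soff
  for (j in seq_len(layer$k^2)) {
    sel <- cache$amax == j
    if (any(sel)) {
      tgt <- full_j(j)[sel]
      dxv[tgt] <- dxv[tgt] + dov[sel]
    }
  }
  list(dx = array(dxv, d), grads = list())
}

upsample_forward <- function(layer, x) {
  f <- layer$factor
  d <- dim(x)
  out <- x[rep(seq_len(d[1]), each = f), rep(seq_len(d[2]), each = f), , , drop = FALSE]
  list(out = out, cache = list(in_dim = d))
}

upsample_backward <- function(layer, cache, dout) {
  f <- layer$factor; d <- cache$in_dim
  dx <- array(0, d)
  for (i in seq_len(f)) for (j in seq_len(f)) {
    dx <- dx + dout[seq(i, by = f, length.out = d[1]),
                    seq(j, by = f, length.out = d[2]), , , drop = FALSE]
  }
  list(dx = dx, grads = list())
}

# Adaptive average pooling to `out` x `out` cells; region boundaries follow
# the floor/ceil convention so it degrades to identity when H = W = out.
adapt_regions <- function(n, out) {
  lapply(seq_len(out), function(i) {
    (floor((i - 1) * n / out) + 1L):ceiling(i * n / out)
  })
}

adaptpool_forward <- function(layer, x) {
  d <- dim(x); o <- layer$out
  ri <- adapt_regions(d[1], o); cj <- adapt_regions(d[2], o)
  out <- array(0, c(o, o, d[3], d[4]))
  for (i in seq_len(o)) for (j in seq_len(o)) {
    out[i, j, , ] <- apply(x[ri[[i]], cj[[j]], , , drop = FALSE], c(3, 4), mean)
  }
  list(out = out, cache = list(in_dim = d))
}

adaptpool_backward <- function(layer, cache, dout) {
  d <- cache$in_dim; o <- layer$out
  ri <- adapt_regions(d[1], o); cj <- adapt_regions(d[2], o)
  dx <- array(0, d)
  for (i in seq_len(o)) for (j in seq_len(o)) {
    cell <- dout[i, j, , , drop = FALSE]
    m <- length(ri[[i]]) * length(cj[[j]])
    add <- aperm(array(cell[1, 1, , ] / m,
                       c(d[3], d[4], length(ri[[i]]), length(cj[[j]]))),
                 c(3, 4, 1, 2))
    dx[ri[[i]], cj[[j]], , ] <- dx[ri[[i]], cj[[j]], , , drop = FALSE] + add
  }
  list(dx = dx, grads = list())
}

# dense / regularization -------------------------------------------------------

flatten_forward <- function(layer, x) {
  d <- dim(x)
  list(out = matrix(x, prod(d[1:3]), d[4]), cache = list(in_dim = d))
}

flatten_backward <- function(layer, cache, dout) {
  list(dx = array(dout, cache$in_dim), grads = list())
}

fc_forward <- function(layer, x) {
  out <- layer$params$W %*% x + layer$params$b
  relu_mask <- NULL
  if (identical(layer$activation, "relu")) {
    relu_mask <- out > 0
    out <- out * relu_mask
  }
  list(out = out, cache = list(x = x, relu_mask = relu_mask))
}

fc_backward <- function(layer, cache, dout) {
  if (!is.null(cache$relu_mask)) dout <- dout * cache$relu_mask
  list(dx = crossprod(layer$params$W, dout),
       grads = list(W = tcrossprod(dout, cache$x), b = rowSums(dout)))
}

dropout_forward <- function(layer, x, training) {
  if (!training || layer$p <= 0) {
    return(list(out = x, cache = list(mask = NULL)))
  }
  keep <- 1 - layer$p
  mask <- (runif(length(x)) < keep) / keep
  dim(mask) <- dim(x) %||% length(x)
  list(out = x * mask, cache = list(mask = mask))
}

dropout_backward <- function(layer, cache, dout) {
  dx <- if (is.null(cache$mask)) dout else dout * cache$mask
  list(dx = dx, grads = list())
}

# attention stages -------------------------------------------------------------

# Global average pool over space: (H,W,C,N) -> (C,N)
gap_spatial <- function(x) {
  d <- dim(x)
  matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4])
}

se_forward_internal <- function(layer, x) {
  d <- dim(x); HW <- d[1] * d[2]
  s <- gap_spatial(x)
  z1 <- layer$params$W1 %*% s + layer$params$b1
  a <- z1 * (z1 > 0)
  z2 <- layer$params$W2 %*% a + layer$params$b2
  g <- sigmoid(z2)
  gv <- rep(as.vector(g), each = HW)
  out <- x * gv
  list(out = out, cache = list(x = x, s = s, z1 = z1, a = a, g = g, d = d))
}

se_backward_internal <- function(layer, cache, dout) {
  d <- cache$d; HW <- d[1] * d[2]
  g <- cache$g
  gv <- rep(as.vector(g), each = HW)
  dx <- dout * gv
  dg <- matrix(colSums(matrix(dout * cache$x, HW, d[3] * d[4])), d[3], d[4])
  dz2 <- dg * g * (1 - g)
  dW2 <- tcrossprod(dz2, cache$a)
  db2 <- rowSums(dz2)
  da <- crossprod(layer$params$W2, dz2)
  dz1 <- da * (cache$z1 > 0)
  dW1 <- tcrossprod(dz1, cache$s)
  db1 <- rowSums(dz1)
  ds <- crossprod(layer$params$W1, dz1)
  dx <- dx + rep(as.vector(ds), each = HW) / HW
  list(dx = dx, grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

eca_forward_internal <- function(layer, x) {
  d <- dim(x); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  k <- layer$k; pad <- (k - 1L) %/% 2L
  s <- gap_spatial(x)
  sp <- rbind(matrix(0, pad, N), s, matrix(0, pad, N))
  z <- matrix(0, C, N)
  for (j in seq_len(k)) z <- z + layer$params$w[j] * sp[j:(j + C - 1L), , drop = FALSE]
  g <- sigmoid(z)
  gv <- rep(as.vector(g), each = HW)
  list(out = x * gv, cache = list(x = x, sp = sp, g = g, d = d))
}

eca_backward_internal <- function(layer, cache, dout) {
  d <- cache$d; HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  k <- layer$k; pad <- (k - 1L) %/% 2L
  g <- cache$g
  gv <- rep(as.vector(g), each = HW)
  dx <- dout * gv
  dg <- matrix(colSums(matrix(dout * cache$x, HW, C * N)), C, N)
  dz <- dg * g * (1 - g)
  dw <- vapply(seq_len(k), function(j)
    sum(cache$sp[j:(j + C - 1L), , drop = FALSE] * dz), numeric(1))
  wrev <- rev(layer$params$w)
  dzp <- rbind(matrix(0, pad, N), dz, matrix(0, pad, N))
  ds <- matrix(0, C, N)
  for (j in seq_len(k)) ds <- ds + wrev[j] * dzp[j:(j + C - 1L), , drop = FALSE]
  dx <- dx + rep(as.vector(ds), each = HW) / HW
  list(dx = dx, grads = list(w = dw))
}

cbam_forward_internal <- function(layer, x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]; HW <- H * W
  m <- matrix(x, HW, C * N)
  s_avg <- matrix(colMeans(m), C, N)
  amax_sp <- max.col(t(m), ties.method = "first")   # spatial argmax per (c, n)
  s_max <- matrix(m[cbind(amax_sp, seq_len(C * N))], C, N)
  mlp <- function(s) {
    z1 <- layer$params$W1 %*% s + layer$params$b1
    a <- z1 * (z1 > 0)
    list(z1 = z1, a = a, z2 = layer$params$W2 %*% a + layer$params$b2)
  }
  pa <- mlp(s_avg); pm <- mlp(s_max)
  gch <- sigmoid(pa$z2 + pm$z2)
  gchv <- rep(as.vector(gch), each = HW)
  x1 <- x * gchv
  # spatial stage: channel-mean and channel-max maps, stacked (avg, max)
  arr <- array(x1, c(HW, C, N))
  avgc <- apply(arr, 3, rowMeans)                    # HW x N
  amax_ch <- sapply(seq_len(N), function(n) max.col(arr[, , n, drop = TRUE], ties.method = "first"))
  amax_ch <- matrix(amax_ch, HW, N)
  maxc <- matrix(arr[cbind(rep(seq_len(HW), N), as.vector(amax_ch),
                           rep(seq_len(N), each = HW))], HW, N)
  sp_in <- array(0, c(H, W, 2L, N))
  sp_in[, , 1L, ] <- avgc
  sp_in[, , 2L, ] <- maxc
  conv <- list(type = "conv", name = "cbam_spatial", k = layer$spatial_kernel,
               stride = 1L, pad = (layer$spatial_kernel - 1L) %/% 2L,
               c_in = 2L, c_out = 1L, activation = "linear",
               params = list(W = layer$params$Wsp, b = layer$params$bsp))
  cf <- conv_forward(conv, sp_in)
  gsp <- sigmoid(cf$out)                             # H x W x 1 x N
  gsp_mat <- matrix(gsp, HW, N)
  gspv <- as.vector(aperm(array(gsp_mat, c(HW, N, C)), c(1, 3, 2)))
  out <- x1 * gspv
  list(out = out,
       cache = list(x = x, d = d, s_avg = s_avg, s_max = s_max,
                    amax_sp = amax_sp, pa = pa, pm = pm, gch = gch, x1 = x1,
                    amax_ch = amax_ch, conv = conv, conv_cache = cf$cache,
                    gsp_mat = gsp_mat, gspv = gspv))
}

cbam_backward_internal <- function(layer, cache, dout) {
  d <- cache$d; H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]; HW <- H * W
  # spatial gate
  dx1 <- dout * cache$gspv
  tmp <- array(dout * cache$x1, c(HW, C, N))
  dgsp <- apply(tmp, 3, rowSums)                     # HW x N
  dconv_out <- array(dgsp * cache$gsp_mat * (1 - cache$gsp_mat), c(H, W, 1L, N))
  cb <- conv_backward(cache$conv, cache$conv_cache, dconv_out)
  davgc <- matrix(cb$dx[, , 1L, ], HW, N)
  dmaxc <- matrix(cb$dx[, , 2L, ], HW, N)
  dx1 <- dx1 + as.vector(aperm(array(davgc / C, c(HW, N, C)), c(1, 3, 2)))
  lin <- rep(seq_len(HW), N) + (as.vector(cache$amax_ch) - 1L) * HW +
    (rep(seq_len(N), each = HW) - 1L) * HW * C
  dx1v <- as.vector(dx1)
  dx1v[lin] <- dx1v[lin] + as.vector(dmaxc)
  dx1 <- array(dx1v, d)
  # channel gate
  gch <- cache$gch
  gchv <- rep(as.vector(gch), each = HW)
  dx <- dx1 * gchv
  dgch <- matrix(colSums(matrix(dx1 * cache$x, HW, C * N)), C, N)
  dz <- dgch * gch * (1 - gch)
  back_mlp <- function(p, s) {
    dW2 <- tcrossprod(dz, p$a)
    db2 <- rowSums(dz)
    da <- crossprod(layer$params$W2, dz)
    dz1 <- da * (p$z1 > 0)
    dW1 <- tcrossprod(dz1, s)
    db1 <- rowSums(dz1)
    ds <- crossprod(layer$params$W1, dz1)
    list(dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2, ds = ds)
  }
  ba <- back_mlp(cache$pa, cache$s_avg)
  bm <- back_mlp(cache$pm, cache$s_max)
  dx <- dx + rep(as.vector(ba$ds), each = HW) / HW
  dxv <- as.vector(dx)
  # s_max[c,n] = x[amax_sp, c, n]: route its gradient to the argmax pixel
  m_idx <- (seq_len(C * N) - 1L) * HW + cache$amax_sp
  dxv[m_idx] <- dxv[m_idx] + as.vector(bm$ds)
  dx <- array(dxv, d)
  list(dx = dx,
       grads = list(W1 = ba$dW1 + bm$dW1, b1 = ba$db1 + bm$db1,
                    W2 = ba$dW2 + bm$dW2, b2 = ba$db2 + bm$db2,
                    Wsp = cb$grads$W, bsp = cb$grads$b))
}

# dispatch ---------------------------------------------------------------------

layer_forward <- function(layer, x, training = FALSE) {
  switch(layer$type,
    conv = conv_forward(layer, x, keep_patches = training),
    maxpool = maxpool_forward(layer, x),
    upsample = upsample_forward(layer, x),
    adaptpool = adaptpool_forward(layer, x),
    flatten = flatten_forward(layer, x),
    dropout = dropout_forward(layer, x, training),
    fc = fc_forward(layer, x),
    se = se_forward_internal(layer, x),
    eca = eca_forward_internal(layer, x),
    cbam = cbam_forward_internal(layer, x),
    csb_stop(paste0("unknown layer type: ", layer$type), "csbnet_internal")
  )
}

layer_backward <- function(layer, cache, dout) {
  switch(layer$type,
    conv = conv_backward(layer, cache, dout),
    maxpool = maxpool_backward(layer, cache, dout),
    upsample = upsample_backward(layer, cache, dout),
    adaptpool = adaptpool_backward(layer, cache, dout),
    flatten = flatten_backward(layer, cache, dout),
    dropout = dropout_backward(layer, cache, dout),
    fc = fc_backward(layer, cache, dout),
    se = se_backward_internal(layer, cache, dout),
    eca = eca_backward_internal(layer, cache, dout),
    cbam = cbam_backward_internal(layer, cache, dout),
    csb_stop(paste0("unknown layer type: ", layer$type), "csbnet_internal")
  )
}

# trainable parameter count of a single layer (biases included where present)
layer_param_count <- function(layer) {
  sum(vapply(layer$params, function(p) if (is.null(p)) 0L else length(p), integer(1)))
}
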