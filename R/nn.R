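# Minimal 3D neural-network engine.
#
# The pipeline needs three things no installed package provides together:
# small 3D convolutional nets, exact gradients of the scalar output with
# respect to every input voxel (for sensitivity maps), and bit-reproducible
# training under a seed. The engine below implements them directly: each
# 3x3x3 convolution is expressed as a gather (precomputed integer index
# plan into the zero-padded grid) followed by one BLAS matrix product, and
# the transposed convolution / input gradient reuse the same plan as the
# adjoint scatter. Volumes travel as (n_voxels x n_channels) matrices in
# column-major grid order; dense activations travel as plain vectors.
# Everything is double precision and single-threaded, so identical seeds
# give bit-identical results.

# ---- index plans -----------------------------------------------------------

# Plan for a kernel-3, pad-1 convolution mapping `dims` -> ceil(dims/stride).
# P[o, t] is the linear index (into the padded grid) of the t-th kernel tap
# for output voxel o; `inner` maps unpadded voxels into the padded grid.
conv_plan <- function(dims, stride) {
  dims <- as.integer(dims)
  stride <- as.integer(stride)
  pd <- dims + 2L
  od <- (dims - 1L) %/% stride + 1L
  gi <- (seq_len(od[1]) - 1L) * stride + 1L
  gj <- (seq_len(od[2]) - 1L) * stride + 1L
  gk <- (seq_len(od[3]) - 1L) * stride + 1L
  cent <- cbind(
    rep(gi, times = od[2] * od[3]),
    rep(rep(gj, each = od[1]), times = od[3]),
    rep(gk, each = od[1] * od[2])
  )
  nout <- prod(od)
  P <- matrix(0L, nout, 27L)
  t <- 0L
  for (dk in 0:2) for (dj in 0:2) for (di in 0:2) {
    t <- t + 1L
    P[, t] <- (cent[, 1] + di) +
      (cent[, 2] + dj - 1L) * pd[1] +
      (cent[, 3] + dk - 1L) * pd[1] * pd[2]
  }
  ii <- 2:(pd[1] - 1L)
  jj <- 2:(pd[2] - 1L)
  kk <- 2:(pd[3] - 1L)
  inner <- as.vector(outer(outer(ii, (jj - 1L) * pd[1], "+"),
                           (kk - 1L) * pd[1] * pd[2], "+"))
  list(P = P, inner = inner, in_dims = dims, out_dims = od,
       npad = prod(pd), nout = nout, nvox = prod(dims))
}

# Gather the 27 kernel taps of every output voxel: x (nvox x cin) ->
# cols (nout x 27*cin).
conv_gather <- function(x, plan, cin) {
  cols <- matrix(0, plan$nout, 27L * cin)
  xp <- numeric(plan$npad)
  for (c in seq_len(cin)) {
    xp[] <- 0
    xp[plan$inner] <- x[, c]
    cols[, ((c - 1L) * 27L + 1L):(c * 27L)] <- xp[plan$P]
  }
  cols
}

# Adjoint of conv_gather: cols (nout x 27*cin) -> x (nvox x cin).
# For a fixed kernel tap the target indices are distinct, so each of the
# 27 accumulations is a plain vectorized add.
conv_scatter <- function(cols, plan, cin) {
  x <- matrix(0, plan$nvox, cin)
  dxp <- numeric(plan$npad)
  for (c in seq_len(cin)) {
    dxp[] <- 0
    for (t in 1:27) {
      idx <- plan$P[, t]
      dxp[idx] <- dxp[idx] + cols[, (c - 1L) * 27L + t]
    }
    x[, c] <- dxp[plan$inner]
  }
  x
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}

# ---- layers ----------------------------------------------------------------
# A layer is a list with $type, optional parameters $W/$b, and geometry.
# Forward functions return list(out, cache); backward functions take the
# cache and upstream gradient and return list(dx, dW, db).

layer_conv <- function(cin, cout, dims, stride) {
  list(type = "conv", cin = cin, cout = cout,
       plan = conv_plan(dims, stride),
       W = he_init(27L * cin, cout, 27L * cin),
       b = numeric(cout))
}

layer_convT <- function(cin, cout, dims_out) {
  # adjoint of a stride-2 conv on the *output* grid; W indexed like the
  # corresponding forward conv (27*cout x cin)
  list(type = "convT", cin = cin, cout = cout,
       plan = conv_plan(dims_out, 2L),
       W = he_init(27L * cout, cin, 27L * cin),
       b = numeric(cout))
}

layer_relu <- function() list(type = "relu")

layer_flatten <- function() list(type = "flatten")

layer_unflatten <- function(nvox, ch) list(type = "unflatten", nvox = nvox, ch = ch)

# Fixed (non-trainable) element-wise standardization: out = (x - mu) / sd.
# Used between a frozen encoder and the regression head so the head sees
# unit-scale features regardless of the encoder's output scale.
layer_affine <- function(mu, sd) {
  sd[sd == 0] <- 1
  list(type = "affine", mu = mu, sd = sd)
}

layer_dense <- function(nin, nout) {
  list(type = "dense", nin = nin, nout = nout,
       W = he_init(nin, nout, nin),
       b = numeric(nout))
}

layer_forward <- function(layer, x) {
  switch(layer$type,
    conv = {
      cols <- conv_gather(x, layer$plan, layer$cin)
      out <- cols %*% layer$W + rep(layer$b, each = layer$plan$nout)
      list(out = out, cache = cols)
    },
    convT = {
      u <- x %*% t(layer$W)                      # (n_small x 27*cout)
      out <- conv_scatter(u, layer$plan, layer$cout) +
        rep(layer$b, each = layer$plan$nvox)
      list(out = out, cache = x)
    },
    relu = {
      out <- x
      out[out < 0] <- 0
      list(out = out, cache = x > 0)
    },
    affine = list(out = (x - layer$mu) / layer$sd, cache = NULL),
    flatten = list(out = as.vector(x), cache = dim(x)),
    unflatten = list(out = matrix(x, layer$nvox, layer$ch), cache = NULL),
    dense = {
      list(out = as.vector(crossprod(layer$W, x)) + layer$b, cache = x)
    },
    stop("unknown layer type: ", layer$type)
  )
}

layer_backward <- function(layer, cache, dy) {
  switch(layer$type,
    conv = {
      dW <- crossprod(cache, dy)
      db <- colSums(dy)
      dcols <- tcrossprod(dy, layer$W)
      dx <- conv_scatter(dcols, layer$plan, layer$cin)
      list(dx = dx, dW = dW, db = db)
    },
    convT = {
      cols <- conv_gather(dy, layer$plan, layer$cout)
      dx <- cols %*% layer$W
      dW <- crossprod(cols, cache)
      db <- colSums(dy)
      list(dx = dx, dW = dW, db = db)
    },
    relu = list(dx = dy * cache),
    affine = list(dx = dy / layer$sd),
    flatten = list(dx = matrix(dy, cache[1], cache[2])),
    unflatten = list(dx = as.vector(dy)),
    dense = {
      list(dx = as.vector(layer$W %*% dy),
           dW = outer(cache, dy), db = dy)
    }
  )
}

net_forward <- function(layers, x, want_caches = TRUE) {
  caches <- if (want_caches) vector("list", length(layers)) else NULL
  for (i in seq_along(layers)) {
    fw <- layer_forward(layers[[i]], x)
    x <- fw$out
    if (want_caches) caches[[i]] <- fw$cache
  }
  list(out = x, caches = caches)
}

# Backpropagate dy through the whole stack; returns per-layer parameter
# gradients and the gradient with respect to the input.
net_backward <- function(layers, caches, dy) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    bw <- layer_backward(layers[[i]], caches[[i]], dy)
    dy <- bw$dx
    if (!is.null(bw$dW)) grads[[i]] <- list(dW = bw$dW, db = bw$db)
  }
  list(grads = grads, dinput = dy)
}

net_params <- function(layers) {
  lapply(layers, function(l) if (!is.null(l$W)) list(W = l$W, b = l$b))
}

net_set_params <- function(layers, params) {
  for (i in seq_along(layers)) {
    if (!is.null(params[[i]])) {
      layers[[i]]$W <- params[[i]]$W
      layers[[i]]$b <- params[[i]]$b
    }
  }
  layers
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  lapply(params, function(p) {
    if (is.null(p)) return(NULL)
    list(mW = p$W * 0, vW = p$W * 0, mb = p$b * 0, vb = p$b * 0)
  })
}

# One Adam update over the layer stack; `trainable` is a logical vector per
# layer (frozen layers are skipped entirely).
adam_step <- function(layers, grads, state, t, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      trainable = NULL) {
  for (i in seq_along(layers)) {
    if (is.null(grads[[i]])) next
    if (!is.null(trainable) && !trainable[i]) next
    s <- state[[i]]
    g <- grads[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    mhW <- s$mW / (1 - beta1^t)
    vhW <- s$vW / (1 - beta2^t)
    mhb <- s$mb / (1 - beta1^t)
    vhb <- s$vb / (1 - beta2^t)
    layers[[i]]$W <- layers[[i]]$W - lr * mhW / (sqrt(vhW) + eps)
    layers[[i]]$b <- layers[[i]]$b - lr * mhb / (sqrt(vhb) + eps)
    state[[i]] <- s
  }
  list(layers = layers, state = state)
}
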