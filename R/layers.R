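# Neural-network building blocks with hand-derived backward passes.
#
# Layers are plain lists (type, params, buffers, meta). Data layouts,
# all column-major with the batch first and the feature maps last:
#   spatial stage   [n, T, P, K]  (P = remaining spatial positions)
#   temporal stage  [n, T, S]
#   head            [n, features]
# Convolutions are "valid" (no padding) and have no bias terms; batch
# normalization follows each activation and makes biases redundant in
# the convolutional stages.

SELU_LAMBDA <- 1.0507009873554805
SELU_ALPHA <- 1.6732632423543772

#' Elementwise activation functions
#'
#' The three activations selectable in the architectures: the rectified
#' linear unit, the exponential linear unit, and the scaled ELU with the
#' standard self-normalizing constants (lambda ~= 1.0507, alpha ~= 1.6733).
#'
#' @param name one of `"relu"`, `"elu"`, `"selu"` (case-insensitive).
#' @param x numeric vector or array.
#' @return `activation()` returns the transformed values.
#' @export
activation <- function(name, x) {
  switch(tolower(name),
    relu = pmax(x, 0),
    elu = ifelse(x > 0, x, exp(pmin(x, 0)) - 1),
    selu = SELU_LAMBDA * ifelse(x > 0, x, SELU_ALPHA * (exp(pmin(x, 0)) - 1)),
    abort_config(sprintf("unknown activation '%s' (use relu, elu or selu)", name))
  )
}

activation_grad <- function(name, x) {
  switch(tolower(name),
    relu = (x > 0) * 1,
    elu = ifelse(x > 0, 1, exp(pmin(x, 0))),
    selu = SELU_LAMBDA * ifelse(x > 0, 1, SELU_ALPHA * exp(pmin(x, 0))),
    abort_config(sprintf("unknown activation '%s'", name))
  )
}

## ---- layer constructors -------------------------------------------------

layer_spatial_conv <- function(taps, k_in, k_out, stage = "spatial") {
  list(type = "spatial_conv", stage = stage,
       params = list(W = matrix(0, taps * k_in, k_out)),
       buffers = list(),
       meta = list(taps = taps, k_in = k_in, k_out = k_out))
}

layer_temporal_conv <- function(taps, k_in, k_out, stage = "temporal") {
  list(type = "temporal_conv", stage = stage,
       params = list(W = matrix(0, taps * k_in, k_out)),
       buffers = list(),
       meta = list(taps = taps, k_in = k_in, k_out = k_out))
}

layer_act <- function(fun, stage) {
  list(type = "act", stage = stage, params = list(), buffers = list(),
       meta = list(fun = fun))
}

layer_bnorm <- function(k, stage, momentum = 0.1, eps = 1e-5) {
  list(type = "bnorm", stage = stage,
       params = list(gamma = rep(1, k), beta = rep(0, k)),
       buffers = list(run_mean = rep(0, k), run_var = rep(1, k)),
       meta = list(k = k, momentum = momentum, eps = eps))
}

layer_squeeze <- function(stage = "spatial") {
  list(type = "squeeze", stage = stage, params = list(), buffers = list(),
       meta = list())
}

layer_avg_pool <- function(width, stage = "temporal") {
  list(type = "avg_pool", stage = stage, params = list(), buffers = list(),
       meta = list(width = width))
}

layer_flatten <- function(stage = "head") {
  list(type = "flatten", stage = stage, params = list(), buffers = list(),
       meta = list())
}

layer_dense <- function(n_in, n_out, stage = "head") {
  list(type = "dense", stage = stage,
       params = list(W = matrix(0, n_in, n_out), b = rep(0, n_out)),
       buffers = list(),
       meta = list(n_in = n_in, n_out = n_out))
}

layer_dropout <- function(rate, spatial = FALSE, stage) {
  list(type = "dropout", stage = stage, params = list(), buffers = list(),
       meta = list(rate = rate, spatial = spatial))
}

## ---- forward passes -----------------------------------------------------

# Unfold the spatial-position axis of [n, T, P, Ki] into im2col form
# [n*T*P', taps*Ki]; column block l holds x[., ., p+l-1, .].
im2col_spatial <- function(x, taps) {
  d <- dim(x)
  m <- d[1L] * d[2L]; P <- d[3L]; Ki <- d[4L]
  Xc <- x[get_im2col_idx(m, P, Ki, taps)]
  dim(Xc) <- c(m * (P - taps + 1L), taps * Ki)
  Xc
}

fwd_spatial_conv <- function(layer, x, training) {
  d <- dim(x)
  taps <- layer$meta$taps
  if (d[4L] != layer$meta$k_in || d[3L] < taps)
    abort_contract("input shape does not match spatial convolution geometry")
  Pp <- d[3L] - taps + 1L
  Xc <- im2col_spatial(x, taps)
  out <- array(Xc %*% layer$params$W, c(d[1L], d[2L], Pp, layer$meta$k_out))
  list(out = out, cache = list(Xc = Xc, dim_in = d, Pp = Pp))
}

bwd_spatial_conv <- function(layer, cache, dout) {
  d <- cache$dim_in; taps <- layer$meta$taps; Ki <- layer$meta$k_in
  Pp <- cache$Pp
  dmat <- matrix(dout, nrow(cache$Xc), layer$meta$k_out)
  dW <- crossprod(cache$Xc, dmat)
  dXc <- dmat %*% t(layer$params$W)
  dx <- array(0, d)
  for (l in seq_len(taps)) {
    blk <- array(dXc[, (l - 1L) * Ki + seq_len(Ki)], c(d[1L], d[2L], Pp, Ki))
    dx[, , l:(l + Pp - 1L), ] <- dx[, , l:(l + Pp - 1L), , drop = FALSE] + blk
  }
  list(dx = dx, grads = list(W = dW))
}

# Memoized linear-index tables for the im2col gathers. One gather (a
# single C-level subscript) replaces a per-tap slicing loop, which is
# the difference between an R-bound and a BLAS-bound training step.
.megnet_cache <- new.env(parent = emptyenv())

get_im2col_idx <- function(m, L, K, taps) {
  key <- paste(m, L, K, taps, sep = "_")
  idx <- .megnet_cache[[key]]
  if (!is.null(idx)) return(idx)
  Lp <- L - taps + 1L
  base <- rep.int(seq_len(m), Lp) + (rep(seq_len(Lp), each = m) - 1L) * m
  off <- rep((seq_len(taps) - 1L) * m, each = K) +
    rep((seq_len(K) - 1L) * (m * L), times = taps)
  # kept dimensionless: a matrix subscript would trigger coordinate indexing
  idx <- rep.int(base, taps * K) + rep(off, each = m * Lp)
  if (length(ls(.megnet_cache)) > 24L) rm(list = ls(.megnet_cache), envir = .megnet_cache)
  .megnet_cache[[key]] <- idx
  idx
}

im2col_temporal <- function(x, taps) {
  d <- dim(x)
  Xc <- x[get_im2col_idx(d[1L], d[2L], d[3L], taps)]
  dim(Xc) <- c(d[1L] * (d[2L] - taps + 1L), taps * d[3L])
  Xc
}

fwd_temporal_conv <- function(layer, x, training) {
  d <- dim(x); taps <- layer$meta$taps
  if (d[3L] != layer$meta$k_in || d[2L] < taps)
    abort_contract("input shape does not match temporal convolution geometry")
  Tp <- d[2L] - taps + 1L
  Xc <- im2col_temporal(x, taps)
  out <- array(Xc %*% layer$params$W, c(d[1L], Tp, layer$meta$k_out))
  list(out = out, cache = list(Xc = Xc, dim_in = d, Tp = Tp))
}

# Input gradient as a full convolution of the (zero-padded) output
# gradient with the tap-reversed kernels -- one gather and one GEMM.
bwd_temporal_conv <- function(layer, cache, dout) {
  d <- cache$dim_in; taps <- layer$meta$taps; S <- layer$meta$k_in
  n <- d[1L]; Tlen <- d[2L]; Tp <- cache$Tp
  Ko <- layer$meta$k_out
  dmat <- matrix(dout, nrow(cache$Xc), Ko)
  dW <- crossprod(cache$Xc, dmat)
  if (taps == 1L) {
    dx <- array(dmat %*% t(layer$params$W), d)
  } else {
    Lpad <- Tp + 2L * (taps - 1L)
    dpad <- array(0, c(n, Lpad, Ko))
    dpad[, (taps - 1L) + seq_len(Tp), ] <- dout
    Dc <- dpad[get_im2col_idx(n, Lpad, Ko, taps)]
    dim(Dc) <- c(n * Tlen, taps * Ko)
    Warr <- array(layer$params$W, c(S, taps, Ko))
    Wrev <- matrix(aperm(Warr[, taps:1, , drop = FALSE], c(3L, 2L, 1L)),
                   taps * Ko, S)
    dx <- array(Dc %*% Wrev, d)
  }
  list(dx = dx, grads = list(W = dW))
}

fwd_act <- function(layer, x, training) {
  if (identical(layer$meta$fun, "identity"))
    return(list(out = x, cache = list(x = x)))
  list(out = activation(layer$meta$fun, x), cache = list(x = x))
}

bwd_act <- function(layer, cache, dout) {
  if (identical(layer$meta$fun, "identity"))
    return(list(dx = dout, grads = list()))
  list(dx = dout * activation_grad(layer$meta$fun, cache$x), grads = list())
}

fwd_bnorm <- function(layer, x, training) {
  k <- layer$meta$k; eps <- layer$meta$eps
  d <- dim(x) %||% c(length(x), 1L)
  x2 <- matrix(x, ncol = k)
  if (training) {
    mu <- colMeans(x2)
    va <- colMeans(x2^2) - mu^2
    mom <- layer$meta$momentum
    layer$buffers$run_mean <- (1 - mom) * layer$buffers$run_mean + mom * mu
    layer$buffers$run_var <- (1 - mom) * layer$buffers$run_var + mom * va
  } else {
    mu <- layer$buffers$run_mean
    va <- layer$buffers$run_var
  }
  invstd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(x2, 2L, mu, "-"), 2L, invstd, "*")
  out2 <- sweep(sweep(xhat, 2L, layer$params$gamma, "*"), 2L, layer$params$beta, "+")
  list(out = array(out2, d),
       cache = list(xhat = xhat, invstd = invstd, dim = d, training = training),
       layer = layer)
}

bwd_bnorm <- function(layer, cache, dout) {
  k <- layer$meta$k
  d2 <- matrix(dout, ncol = k)
  xhat <- cache$xhat
  dgamma <- colSums(d2 * xhat)
  dbeta <- colSums(d2)
  dxhat <- sweep(d2, 2L, layer$params$gamma, "*")
  if (cache$training) {
    m <- nrow(d2)
    dx2 <- sweep(dxhat, 2L, colSums(dxhat) / m, "-") -
      sweep(xhat, 2L, colSums(dxhat * xhat) / m, "*")
    dx2 <- sweep(dx2, 2L, cache$invstd, "*")
  } else {
    dx2 <- sweep(dxhat, 2L, cache$invstd, "*")
  }
  list(dx = array(dx2, cache$dim), grads = list(gamma = dgamma, beta = dbeta))
}

fwd_squeeze <- function(layer, x, training) {
  d <- dim(x)
  if (d[3L] != 1L)
    abort_contract("spatial stage did not collapse to a single position")
  list(out = array(x, c(d[1L], d[2L], d[4L])), cache = list(dim_in = d))
}

bwd_squeeze <- function(layer, cache, dout)
  list(dx = array(dout, cache$dim_in), grads = list())

fwd_avg_pool <- function(layer, x, training) {
  w <- layer$meta$width
  d <- dim(x); n <- d[1L]; Tlen <- d[2L]; S <- d[3L]
  To <- Tlen %/% w
  if (To < 1L) abort_contract("sequence shorter than the pooling width")
  xt <- x[, seq_len(To * w), , drop = FALSE]
  m <- array(xt, c(n, w, To, S))
  out <- colSums(aperm(m, c(2L, 1L, 3L, 4L))) / w
  list(out = array(out, c(n, To, S)), cache = list(dim_in = d, To = To))
}

bwd_avg_pool <- function(layer, cache, dout) {
  w <- layer$meta$width
  d <- cache$dim_in; n <- d[1L]; S <- d[3L]; To <- cache$To
  big <- array(0, c(w, n, To, S))
  sm <- array(dout / w, c(n, To, S))
  for (wi in seq_len(w)) big[wi, , , ] <- sm
  dx <- array(0, d)
  dx[, seq_len(To * w), ] <- array(aperm(big, c(2L, 1L, 3L, 4L)), c(n, To * w, S))
  list(dx = dx, grads = list())
}

fwd_flatten <- function(layer, x, training) {
  d <- dim(x)
  list(out = matrix(x, d[1L], prod(d[-1L])), cache = list(dim_in = d))
}

bwd_flatten <- function(layer, cache, dout)
  list(dx = array(dout, cache$dim_in), grads = list())

fwd_dense <- function(layer, x, training) {
  if (ncol(x) != layer$meta$n_in)
    abort_contract(sprintf("dense layer expected %d inputs, got %d",
                           layer$meta$n_in, ncol(x)))
  out <- sweep(x %*% layer$params$W, 2L, layer$params$b, "+")
  list(out = out, cache = list(x = x))
}

bwd_dense <- function(layer, cache, dout) {
  list(dx = dout %*% t(layer$params$W),
       grads = list(W = crossprod(cache$x, dout), b = colSums(dout)))
}

fwd_dropout <- function(layer, x, training) {
  rate <- layer$meta$rate
  if (!training || rate <= 0) return(list(out = x, cache = list(mask = NULL)))
  d <- dim(x) %||% c(length(x), 1L)
  if (layer$meta$spatial) {
    # drop whole kernel maps: one mask entry per (trial, feature map)
    k <- d[length(d)]
    mask_nk <- matrix(stats::rbinom(d[1L] * k, 1L, 1 - rate) / (1 - rate), d[1L], k)
    mask <- array(0, d)
    if (length(d) == 3L) for (j in seq_len(k)) mask[, , j] <- mask_nk[, j]
    else for (j in seq_len(k)) mask[, , , j] <- mask_nk[, j]
  } else {
    mask <- array(stats::rbinom(prod(d), 1L, 1 - rate) / (1 - rate), d)
  }
  list(out = x * mask, cache = list(mask = mask))
}

bwd_dropout <- function(layer, cache, dout) {
  if (is.null(cache$mask)) return(list(dx = dout, grads = list()))
  list(dx = dout * cache$mask, grads = list())
}

## ---- dispatch -----------------------------------------------------------

layer_forward <- function(layer, x, training) {
  res <- switch(layer$type,
    spatial_conv = fwd_spatial_conv(layer, x, training),
    temporal_conv = fwd_temporal_conv(layer, x, training),
    act = fwd_act(layer, x, training),
    bnorm = fwd_bnorm(layer, x, training),
    squeeze = fwd_squeeze(layer, x, training),
    avg_pool = fwd_avg_pool(layer, x, training),
    flatten = fwd_flatten(layer, x, training),
    dense = fwd_dense(layer, x, training),
    dropout = fwd_dropout(layer, x, training),
    attn_lstm = fwd_attn_lstm(layer, x, training),
    abort_config(sprintf("unknown layer type '%s'", layer$type))
  )
  if (is.null(res$layer)) res$layer <- layer
  res
}

layer_backward <- function(layer, cache, dout) {
  switch(layer$type,
    spatial_conv = bwd_spatial_conv(layer, cache, dout),
    temporal_conv = bwd_temporal_conv(layer, cache, dout),
    act = bwd_act(layer, cache, dout),
    bnorm = bwd_bnorm(layer, cache, dout),
    squeeze = bwd_squeeze(layer, cache, dout),
    avg_pool = bwd_avg_pool(layer, cache, dout),
    flatten = bwd_flatten(layer, cache, dout),
    dense = bwd_dense(layer, cache, dout),
    dropout = bwd_dropout(layer, cache, dout),
    attn_lstm = bwd_attn_lstm(layer, cache, dout),
    abort_config(sprintf("unknown layer type '%s'", layer$type))
  )
}

# Forward through a subset of a layer list; returns updated layers (batch
# norm running statistics move during training).
stack_forward <- function(layers, x, training = FALSE, idx = seq_along(layers)) {
  caches <- vector("list", length(layers))
  for (i in idx) {
    res <- layer_forward(layers[[i]], x, training)
    x <- res$out
    caches[[i]] <- res$cache
    layers[[i]] <- res$layer
  }
  list(out = x, caches = caches, layers = layers)
}

# Backward through the same subset (reverse order); returns per-layer
# parameter gradients and the gradient with respect to the stack input.
stack_backward <- function(layers, caches, dout, idx = seq_along(layers)) {
  grads <- vector("list", length(layers))
  for (i in rev(idx)) {
    res <- layer_backward(layers[[i]], caches[[i]], dout)
    dout <- res$dx
    grads[[i]] <- res$grads
  }
  list(dx = dout, grads = grads)
}

n_layer_params <- function(layer)
  sum(vapply(layer$params, length, integer(1)))

## ---- loss and optimizer -------------------------------------------------

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Cross-entropy of logits against target distributions, optionally with a
# per-example weight (the class-penalty scheme multiplies each example's
# loss by the weight of its true class). Returns the mean loss and the
# gradient with respect to the logits.
softmax_xent <- function(logits, targets, weights = NULL) {
  n <- nrow(logits)
  p <- softmax_rows(logits)
  logp <- log(pmax(p, 1e-12))
  per <- -rowSums(targets * logp)
  if (is.null(weights)) weights <- rep(1, n)
  loss <- mean(per * weights)
  dlogits <- (p - targets) * (weights / n)
  list(loss = loss, dlogits = dlogits)
}

adam_init <- function(layers) {
  lapply(layers, function(l)
    lapply(l$params, function(p) list(m = p * 0, v = p * 0)))
}

# One Adam (or plain SGD) update over every trainable array. L2 weight
# decay applies to convolution and dense weight matrices only -- not to
# biases, normalization parameters, or recurrent weights.
optim_step <- function(layers, grads, state, lr, t, l2 = 0,
                       optimizer = "adam", beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  for (i in seq_along(layers)) {
    if (length(layers[[i]]$params) == 0L || is.null(grads[[i]])) next
    decay_ok <- layers[[i]]$type %in% c("spatial_conv", "temporal_conv", "dense")
    for (nm in names(layers[[i]]$params)) {
      g <- grads[[i]][[nm]]
      if (is.null(g)) next
      p <- layers[[i]]$params[[nm]]
      if (l2 > 0 && decay_ok && nm == "W") g <- g + 2 * l2 * p
      if (optimizer == "adam") {
        st <- state[[i]][[nm]]
        st$m <- beta1 * st$m + (1 - beta1) * g
        st$v <- beta2 * st$v + (1 - beta2) * g^2
        mhat <- st$m / (1 - beta1^t)
        vhat <- st$v / (1 - beta2^t)
        p <- p - lr * mhat / (sqrt(vhat) + eps)
        state[[i]][[nm]] <- st
      } else {
        p <- p - lr * g
      }
      layers[[i]]$params[[nm]] <- p
    }
  }
  list(layers = layers, state = state)
}

# Variance-scaling initialization matched to the activation: He for
# relu/elu, Lecun for selu (required by its self-normalizing property).
init_sd <- function(fan_in, act) {
  if (tolower(act) == "selu") sqrt(1 / fan_in) else sqrt(2 / fan_in)
}

init_layers <- function(layers, act, seed) {
  with_seed(seed, {
    for (i in seq_along(layers)) {
      l <- layers[[i]]
      if (l$type %in% c("spatial_conv", "temporal_conv", "dense")) {
        fan_in <- nrow(l$params$W)
        layers[[i]]$params$W <- matrix(
          stats::rnorm(length(l$params$W), 0, init_sd(fan_in, act)),
          nrow(l$params$W), ncol(l$params$W))
      }
    }
    layers
  })
}
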