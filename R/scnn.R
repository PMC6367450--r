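#' SCNN architecture configuration
#'
#' The spatial-summary convolutional network factorizes single-trial
#' decoding into (i) a stack of non-linear *spatial summary* convolutions
#' that act only across the channel axis at each time point, shrinking
#' the channel dimension layer by layer until it collapses to learned
#' spatial components, (ii) *temporal filtering* convolutions along time
#' (a learned filter bank over the spatial components), optionally
#' average-pooled, and (iii) a fully connected classification head. The
#' factorization mirrors the classical pipeline of channel mixing,
#' filter-bank features, and classification, while remaining trainable
#' end to end.
#'
#' A spatial layer with `taps` kernel taps reduces the number of spatial
#' positions by `taps - 1`; the stack must land on exactly one position.
#' All convolutions are "valid" (no padding) and bias-free; every
#' activation is followed by batch normalization.
#'
#' @param spatial_layers list of `c(taps, kernels)` pairs, first layer
#'   applied to the raw channel axis.
#' @param temporal_filters number of temporal filters `F`.
#' @param temporal_kernel_taps length of each temporal kernel in samples.
#' @param pool_width non-overlapping average-pooling width after the
#'   temporal stage (0 disables pooling).
#' @param activation `"relu"`, `"elu"` or `"selu"`.
#' @param dense_layers integer widths of the hidden fully connected
#'   layers (may be empty).
#' @param dropout_rate ordinary dropout rate on dense layers, in \[0, 1).
#' @param spatial_dropout_rate spatial dropout rate (whole kernel maps)
#'   on convolutional layers, in \[0, 1).
#' @param l2_penalty L2 weight-decay coefficient (>= 0) on convolution
#'   and dense weights.
#' @param n_classes number of output classes.
#' @param batch_norm set `FALSE` to disable batch normalization (used by
#'   equivalence tests; leave `TRUE` for training).
#' @param seed seed for weight initialization.
#' @return an object of class `scnn_config`.
#' @export
scnn_config <- function(spatial_layers, temporal_filters,
                        temporal_kernel_taps, pool_width = 0L,
                        activation = "selu", dense_layers = integer(0),
                        dropout_rate = 0, spatial_dropout_rate = 0,
                        l2_penalty = 0, n_classes = 2L,
                        batch_norm = TRUE, seed = 1L) {
  if (!length(spatial_layers)) abort_config("`spatial_layers` must list at least one layer")
  spatial_layers <- lapply(spatial_layers, function(sl) {
    sl <- as.integer(sl)
    if (length(sl) != 2L || any(sl < 1L))
      abort_config("each spatial layer must be c(taps, kernels) with positive counts")
    sl
  })
  for (nm in c("temporal_filters", "temporal_kernel_taps", "n_classes"))
    if (get(nm) < 1L) abort_config(sprintf("`%s` must be >= 1", nm))
  for (nm in c("dropout_rate", "spatial_dropout_rate")) {
    v <- get(nm)
    if (v < 0 || v >= 1) abort_config(sprintf("`%s` must be in [0, 1)", nm))
  }
  if (l2_penalty < 0) abort_config("`l2_penalty` must be >= 0")
  if (pool_width < 0) abort_config("`pool_width` must be >= 0")
  act <- tolower(activation)
  if (!act %in% c("relu", "elu", "selu", "identity"))
    abort_config(sprintf("unknown activation '%s'", activation))
  structure(list(
    spatial_layers = spatial_layers,
    temporal_filters = as.integer(temporal_filters),
    temporal_kernel_taps = as.integer(temporal_kernel_taps),
    pool_width = as.integer(pool_width),
    activation = act,
    dense_layers = as.integer(dense_layers),
    dropout_rate = dropout_rate,
    spatial_dropout_rate = spatial_dropout_rate,
    l2_penalty = l2_penalty,
    n_classes = as.integer(n_classes),
    batch_norm = isTRUE(batch_norm),
    seed = as.integer(seed)
  ), class = "scnn_config")
}

#' Stage-by-stage shape plan for an SCNN
#'
#' Walks the architecture arithmetic for input geometry `T x C`: each
#' spatial layer with `taps` kernel taps maps `P` positions to
#' `P - taps + 1`, the temporal convolution maps `T` to
#' `T - taps + 1`, and pooling divides by the pool width (floor).
#' Configurations whose spatial stack does not collapse the channel axis
#' to exactly one position are rejected, naming the offending layer.
#'
#' @param cfg an [scnn_config()].
#' @param T_len trial length in samples.
#' @param C number of channels.
#' @return an object of class `shape_plan`: a data frame of per-stage
#'   `(time_len, spatial_positions, kernels)` with the total trainable
#'   parameter count in `attr(, "n_params")`.
#' @export
plan_shapes <- function(cfg, T_len, C) {
  stages <- list()
  add <- function(name, t, p, k) stages[[length(stages) + 1L]] <<-
      data.frame(stage = name, time_len = t, spatial_positions = p, kernels = k)
  P <- C; Ki <- 1L; n_par <- 0L
  add("input", T_len, C, 1L)
  for (i in seq_along(cfg$spatial_layers)) {
    sl <- cfg$spatial_layers[[i]]
    taps <- sl[1L]; Ko <- sl[2L]
    if (taps > P)
      abort_config(sprintf("spatial layer %d has %d taps but only %d positions remain", i, taps, P))
    P <- P - taps + 1L
    n_par <- n_par + taps * Ki * Ko + if (cfg$batch_norm) 2L * Ko else 0L
    Ki <- Ko
    add(sprintf("spatial_%d", i), T_len, P, Ko)
    last_spatial <- i
  }
  if (P != 1L)
    abort_config(sprintf(
      "spatial stack does not collapse the channel axis: %d positions remain after layer %d",
      P, length(cfg$spatial_layers)))
  S <- Ki
  taps_t <- cfg$temporal_kernel_taps
  if (taps_t > T_len)
    abort_config("temporal kernel is longer than the input sequence")
  Tp <- T_len - taps_t + 1L
  Fk <- cfg$temporal_filters
  n_par <- n_par + taps_t * S * Fk + if (cfg$batch_norm) 2L * Fk else 0L
  add("temporal", Tp, 1L, Fk)
  if (cfg$pool_width > 0L) {
    Tp <- Tp %/% cfg$pool_width
    if (Tp < 1L) abort_config("pool width exceeds the temporal sequence length")
    add("pool", Tp, 1L, Fk)
  }
  feat <- Tp * Fk
  add("flatten", 1L, 1L, feat)
  n_in <- feat
  for (j in seq_along(cfg$dense_layers)) {
    w <- cfg$dense_layers[j]
    n_par <- n_par + n_in * w + w + if (cfg$batch_norm) 2L * w else 0L
    add(sprintf("dense_%d", j), 1L, 1L, w)
    n_in <- w
  }
  n_par <- n_par + n_in * cfg$n_classes + cfg$n_classes
  add("logits", 1L, 1L, cfg$n_classes)
  plan <- do.call(rbind, stages)
  attr(plan, "n_params") <- n_par
  class(plan) <- c("shape_plan", class(plan))
  plan
}

#' @export
print.shape_plan <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  cat(sprintf("trainable parameters: %d\n", attr(x, "n_params")))
  invisible(x)
}

#' Build an SCNN model for a given input geometry
#'
#' Instantiates the layer stack described by the configuration, with
#' variance-scaled random initial weights (He scaling for relu/elu,
#' Lecun scaling for selu) drawn from the configuration seed.
#'
#' @param cfg an [scnn_config()].
#' @param T_len trial length in samples.
#' @param C number of channels.
#' @return an object of class `scnn_model`.
#' @export
build_scnn <- function(cfg, T_len, C) {
  plan <- plan_shapes(cfg, T_len, C)  # validates
  layers <- list()
  Ki <- 1L
  for (i in seq_along(cfg$spatial_layers)) {
    sl <- cfg$spatial_layers[[i]]
    layers <- c(layers, list(layer_spatial_conv(sl[1L], Ki, sl[2L])))
    layers <- c(layers, list(layer_act(cfg$activation, "spatial")))
    if (cfg$batch_norm) layers <- c(layers, list(layer_bnorm(sl[2L], "spatial")))
    if (cfg$spatial_dropout_rate > 0)
      layers <- c(layers, list(layer_dropout(cfg$spatial_dropout_rate, TRUE, "spatial")))
    Ki <- sl[2L]
  }
  layers <- c(layers, list(layer_squeeze("spatial")))
  layers <- c(layers, list(layer_temporal_conv(cfg$temporal_kernel_taps, Ki,
                                               cfg$temporal_filters)))
  layers <- c(layers, list(layer_act(cfg$activation, "temporal")))
  if (cfg$batch_norm)
    layers <- c(layers, list(layer_bnorm(cfg$temporal_filters, "temporal")))
  if (cfg$spatial_dropout_rate > 0)
    layers <- c(layers, list(layer_dropout(cfg$spatial_dropout_rate, TRUE, "temporal")))
  if (cfg$pool_width > 0L)
    layers <- c(layers, list(layer_avg_pool(cfg$pool_width, "temporal")))
  layers <- c(layers, list(layer_flatten("head")))
  feat_row <- plan[plan$stage == "flatten", ]
  n_in <- feat_row$kernels
  for (w in cfg$dense_layers) {
    layers <- c(layers, list(layer_dense(n_in, w, "head")))
    layers <- c(layers, list(layer_act(cfg$activation, "head")))
    if (cfg$batch_norm) layers <- c(layers, list(layer_bnorm(w, "head")))
    if (cfg$dropout_rate > 0)
      layers <- c(layers, list(layer_dropout(cfg$dropout_rate, FALSE, "head")))
    n_in <- w
  }
  layers <- c(layers, list(layer_dense(n_in, cfg$n_classes, "head")))
  layers <- init_layers(layers, cfg$activation, cfg$seed)
  structure(list(type = "scnn", cfg = cfg, input_shape = c(T_len, C),
                 layers = layers, plan = plan,
                 classes = NULL),
            class = "scnn_model")
}

#' Number of trainable parameters in a model
#' @param model an `scnn_model` or `rascnn_model`.
#' @return integer count of trainable scalars.
#' @export
count_params <- function(model)
  sum(vapply(model$layers, n_layer_params, integer(1)))

# Coerce a batch to [n, T, C] and check geometry.
check_batch <- function(model, batch) {
  if (length(dim(batch)) == 2L)
    batch <- array(batch, c(1L, dim(batch)))
  d <- dim(batch)
  if (length(d) != 3L || d[2L] != model$input_shape[1L] || d[3L] != model$input_shape[2L])
    abort_contract(sprintf("batch geometry [%s] does not match model input [T=%d, C=%d]",
                           paste(d[-1L], collapse = " x "),
                           model$input_shape[1L], model$input_shape[2L]))
  batch
}

scnn_forward_full <- function(model, batch, training = FALSE) {
  batch <- check_batch(model, batch)
  d <- dim(batch)
  x4 <- array(batch, c(d, 1L))
  stack_forward(model$layers, x4, training)
}

#' SCNN forward pass
#'
#' Evaluation-mode forward pass: deterministic (dropout off, batch
#' normalization using running statistics).
#'
#' @param model an `scnn_model` from [build_scnn()].
#' @param batch numeric array `n x T x C` (a single `T x C` matrix is
#'   promoted to a batch of one).
#' @return logits matrix `n x n_classes`.
#' @export
scnn_forward <- function(model, batch) {
  scnn_forward_full(model, batch, training = FALSE)$out
}

#' Class probabilities from a fitted model
#'
#' @param model a fitted `scnn_model` or `rascnn_model`.
#' @param batch numeric array `n x T x C`.
#' @return matrix `n x n_classes` of softmax probabilities; columns are
#'   named when the model has been trained against labelled data.
#' @export
predict_proba <- function(model, batch) UseMethod("predict_proba")

# Evaluate in fixed-size chunks: bounds memory and reuses the im2col
# index caches built during training.
chunked_logits <- function(model, batch, fwd, chunk = 64L) {
  batch <- check_batch(model, batch)
  n <- dim(batch)[1L]
  if (n <= chunk) return(fwd(model, batch))
  out <- NULL
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    part <- fwd(model, batch[idx, , , drop = FALSE])
    if (is.null(out)) out <- matrix(0, n, ncol(part))
    out[idx, ] <- part
  }
  out
}

#' @export
predict_proba.scnn_model <- function(model, batch) {
  p <- softmax_rows(chunked_logits(model, batch, scnn_forward))
  if (!is.null(model$classes)) colnames(p) <- model$classes
  p
}

#' Wrap an arbitrary prediction function as a model
#'
#' Adapts any function mapping a batch `n x T x C` to class
#' probabilities into the interface expected by the interpretation
#' tools ([obscuring_profile()], [baseline_control()]). Useful for
#' plugging in external classifiers or hand-built oracle models.
#'
#' @param fn function taking a batch array and returning an
#'   `n x n_classes` probability matrix.
#' @param input_shape integer `c(T, C)` the function expects.
#' @param classes character vector of class labels (column order of the
#'   returned probabilities).
#' @return an object of class `custom_model`.
#' @export
custom_model <- function(fn, input_shape, classes) {
  structure(list(type = "custom", fn = fn,
                 input_shape = as.integer(input_shape),
                 classes = as.character(classes)),
            class = "custom_model")
}

#' @export
predict_proba.custom_model <- function(model, batch) {
  if (length(dim(batch)) == 2L) batch <- array(batch, c(1L, dim(batch)))
  p <- model$fn(batch)
  colnames(p) <- model$classes
  p
}

# indices of layers belonging to the given stage(s)
stage_idx <- function(model, stages) {
  which(vapply(model$layers, function(l) l$stage %in% stages, logical(1)))
}

# Output of the spatial-summary stage (learned spatial components over
# time): [n, T, S], evaluation mode.
spatial_output <- function(model, batch) {
  batch <- check_batch(model, batch)
  d <- dim(batch)
  x4 <- array(batch, c(d, 1L))
  stack_forward(model$layers, x4, FALSE, stage_idx(model, "spatial"))$out
}

# Logits from a spatial-stage feature sequence [n, T, S] through the
# temporal and head stages, evaluation mode, with caches for gradients.
logits_from_spatial <- function(model, feats, want_cache = FALSE) {
  idx <- stage_idx(model, c("temporal", "head"))
  res <- stack_forward(model$layers, feats, FALSE, idx)
  if (want_cache) list(out = res$out, caches = res$caches, idx = idx) else res$out
}
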