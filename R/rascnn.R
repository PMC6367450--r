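#' Ra-SCNN architecture configuration
#'
#' The Ra-SCNN keeps the SCNN's spatial-summary and temporal-filtering
#' front end (its dense head removed) and feeds the resulting feature
#' sequence to an LSTM whose input at every step is a *soft-attention*
#' weighted summary of the whole sequence. The attention scores are
#' produced by a small feed-forward network that sees each sequence
#' position's feature vector together with the previous LSTM state, so
#' the recurrence can re-focus on any part of the trial at every step.
#' The front end is trained jointly with the recurrent stage, never
#' frozen.
#'
#' @param front_end an [scnn_config()] whose `dense_layers` is empty;
#'   its spatial/temporal stages become the feature extractor.
#' @param hidden_units LSTM state size (and width of the attention
#'   network's hidden layers).
#' @param attention_layers number of hidden layers in the attention
#'   scoring network (>= 1).
#' @param use_full_sequence classify from the full LSTM output sequence
#'   (`TRUE`) or from the last state only (`FALSE`).
#' @param dense_layers hidden widths of the classification head.
#' @param n_classes number of output classes.
#' @param seed seed for weight initialization.
#' @return an object of class `rascnn_config`.
#' @export
rascnn_config <- function(front_end, hidden_units, attention_layers = 1L,
                          use_full_sequence = FALSE,
                          dense_layers = integer(0), n_classes = 2L,
                          seed = 1L) {
  if (!inherits(front_end, "scnn_config"))
    abort_config("`front_end` must be an scnn_config")
  if (length(front_end$dense_layers))
    abort_config("`front_end$dense_layers` must be empty; the head is replaced")
  if (hidden_units < 1L) abort_config("`hidden_units` must be >= 1")
  if (attention_layers < 1L) abort_config("`attention_layers` must be >= 1")
  structure(list(front_end = front_end,
                 hidden_units = as.integer(hidden_units),
                 attention_layers = as.integer(attention_layers),
                 use_full_sequence = isTRUE(use_full_sequence),
                 dense_layers = as.integer(dense_layers),
                 n_classes = as.integer(n_classes),
                 l2_penalty = front_end$l2_penalty,
                 seed = as.integer(seed)),
            class = "rascnn_config")
}

#' Soft-attention weights from scores
#'
#' Normalizes score rows with a numerically stable softmax
#' (max-subtraction), producing weights in \[0, 1\] that sum to one per
#' feature row.
#'
#' @param e numeric vector of scores, or matrix `features x positions`.
#' @return weights with the same shape as `e`.
#' @export
attention_weights <- function(e) {
  if (!all(is.finite(e))) abort_contract("attention scores must be finite")
  if (is.null(dim(e))) e <- matrix(e, 1L)
  mx <- apply(e, 1L, max)
  w <- exp(e - mx)
  w <- w / rowSums(w)
  if (nrow(w) == 1L) drop(w) else w
}

#' Apply attention weights to a feature sequence
#'
#' Forms the attention-weighted feature summary: for feature `j`,
#' `f_hat[j] = sum_i f[i, j] * alpha[j, i]` over all sequence positions
#' `i`. Uniform weights recover the sequence mean; a one-hot weight row
#' selects a single position.
#'
#' @param f feature sequence, matrix `positions x features`.
#' @param alpha weights: a vector over positions (shared by all
#'   features) or a matrix `features x positions`.
#' @return numeric vector of length `ncol(f)`.
#' @export
attention_apply <- function(f, alpha) {
  if (!is.matrix(f)) f <- matrix(f, ncol = 1L)
  Tp <- nrow(f); J <- ncol(f)
  if (is.null(dim(alpha))) {
    if (length(alpha) != Tp) abort_contract("`alpha` length must match positions")
    return(drop(crossprod(f, alpha)))
  }
  if (ncol(alpha) != Tp || nrow(alpha) != J)
    abort_contract("`alpha` must be features x positions")
  rowSums(alpha * t(f))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

layer_attn_lstm <- function(n_feat, hidden, attention_layers, use_full_sequence) {
  params <- list()
  d_in <- n_feat + hidden
  for (l in seq_len(attention_layers)) {
    params[[paste0("Wa", l)]] <- matrix(0, d_in, hidden)
    params[[paste0("ba", l)]] <- rep(0, hidden)
    d_in <- hidden
  }
  params$Wao <- matrix(0, hidden, n_feat)
  params$bao <- rep(0, n_feat)
  params$Wx <- matrix(0, n_feat, 4L * hidden)
  params$Wh <- matrix(0, hidden, 4L * hidden)
  params$b <- c(rep(0, hidden), rep(1, hidden), rep(0, 2L * hidden))  # forget bias 1
  list(type = "attn_lstm", stage = "recurrent", params = params, buffers = list(),
       meta = list(n_feat = n_feat, hidden = hidden,
                   attention_layers = attention_layers,
                   use_full_sequence = use_full_sequence))
}

# Attention scoring network applied to every (trial, position) row of
# U = [feature vector at the position ; previous LSTM state].
attn_mlp_forward <- function(layer, U) {
  L <- layer$meta$attention_layers
  acts <- vector("list", L)
  A <- U
  for (l in seq_len(L)) {
    A <- tanh(sweep(A %*% layer$params[[paste0("Wa", l)]], 2L,
                    layer$params[[paste0("ba", l)]], "+"))
    acts[[l]] <- A
  }
  e <- sweep(A %*% layer$params$Wao, 2L, layer$params$bao, "+")
  list(e = e, acts = acts)
}

fwd_attn_lstm <- function(layer, x, training) {
  d <- dim(x)
  if (length(d) != 3L || d[3L] != layer$meta$n_feat)
    abort_contract("attention-LSTM input must be [n, T, features]")
  n <- d[1L]; Tp <- d[2L]; Fk <- d[3L]; H <- layer$meta$hidden
  Xmat <- matrix(x, n * Tp, Fk)          # rows grouped position-major, trial fastest
  h <- matrix(0, n, H); cc <- matrix(0, n, H)
  steps <- vector("list", Tp)
  out_seq <- if (layer$meta$use_full_sequence) matrix(0, n, Tp * H) else NULL
  rep_idx <- rep(seq_len(n), Tp)
  for (t in seq_len(Tp)) {
    U <- cbind(Xmat, h[rep_idx, , drop = FALSE])
    mlp <- attn_mlp_forward(layer, U)
    earr <- array(mlp$e, c(n, Tp, Fk))
    # stable softmax over positions per (trial, feature)
    mx <- earr[, 1L, , drop = FALSE]
    if (Tp > 1L) for (p in 2L:Tp) mx <- pmax(mx, earr[, p, , drop = FALSE])
    ex <- array(0, c(n, Tp, Fk)); ssum <- matrix(0, n, Fk)
    for (p in seq_len(Tp)) {
      ex[, p, ] <- exp(earr[, p, ] - mx[, 1L, ])
      ssum <- ssum + ex[, p, ]
    }
    alpha <- array(0, c(n, Tp, Fk))
    xin <- matrix(0, n, Fk)
    for (p in seq_len(Tp)) {
      alpha[, p, ] <- ex[, p, ] / ssum
      xin <- xin + matrix(x[, p, ], n, Fk) * matrix(alpha[, p, ], n, Fk)
    }
    z <- sweep(xin %*% layer$params$Wx + h %*% layer$params$Wh, 2L,
               layer$params$b, "+")
    ig <- sigmoid(z[, seq_len(H), drop = FALSE])
    fg <- sigmoid(z[, H + seq_len(H), drop = FALSE])
    gg <- tanh(z[, 2L * H + seq_len(H), drop = FALSE])
    og <- sigmoid(z[, 3L * H + seq_len(H), drop = FALSE])
    c_prev <- cc; h_prev <- h
    cc <- fg * cc + ig * gg
    tc <- tanh(cc)
    h <- og * tc
    steps[[t]] <- list(U = U, acts = mlp$acts, alpha = alpha, xin = xin,
                       ig = ig, fg = fg, gg = gg, og = og,
                       c_prev = c_prev, h_prev = h_prev, tc = tc)
    if (layer$meta$use_full_sequence) out_seq[, (t - 1L) * H + seq_len(H)] <- h
  }
  out <- if (layer$meta$use_full_sequence) out_seq else h
  list(out = out, cache = list(steps = steps, x = x, dim_in = d, rep_idx = rep_idx))
}

bwd_attn_lstm <- function(layer, cache, dout) {
  d <- cache$dim_in
  n <- d[1L]; Tp <- d[2L]; Fk <- d[3L]; H <- layer$meta$hidden
  L <- layer$meta$attention_layers
  x <- cache$x
  grads <- lapply(layer$params, function(p) p * 0)
  dX <- array(0, d)
  dh_next <- matrix(0, n, H); dc_next <- matrix(0, n, H)
  for (t in rev(seq_len(Tp))) {
    st <- cache$steps[[t]]
    dh <- dh_next
    if (layer$meta$use_full_sequence) {
      dh <- dh + dout[, (t - 1L) * H + seq_len(H), drop = FALSE]
    } else if (t == Tp) {
      dh <- dh + dout
    }
    # LSTM cell backward
    dog <- dh * st$tc
    dc <- dc_next + dh * st$og * (1 - st$tc^2)
    dig <- dc * st$gg
    dgg <- dc * st$ig
    dfg <- dc * st$c_prev
    dc_next <- dc * st$fg
    dz <- cbind(dig * st$ig * (1 - st$ig),
                dfg * st$fg * (1 - st$fg),
                dgg * (1 - st$gg^2),
                dog * st$og * (1 - st$og))
    grads$Wx <- grads$Wx + crossprod(st$xin, dz)
    grads$Wh <- grads$Wh + crossprod(st$h_prev, dz)
    grads$b <- grads$b + colSums(dz)
    dxin <- dz %*% t(layer$params$Wx)
    dh_prev <- dz %*% t(layer$params$Wh)
    # attention-weighted input backward
    dalpha <- array(0, c(n, Tp, Fk))
    for (p in seq_len(Tp)) {
      dalpha[, p, ] <- dxin * matrix(x[, p, ], n, Fk)
      dX[, p, ] <- dX[, p, ] + dxin * matrix(st$alpha[, p, ], n, Fk)
    }
    # softmax over positions backward
    inner <- matrix(0, n, Fk)
    for (p in seq_len(Tp)) inner <- inner +
        matrix(dalpha[, p, ], n, Fk) * matrix(st$alpha[, p, ], n, Fk)
    de <- array(0, c(n, Tp, Fk))
    for (p in seq_len(Tp)) de[, p, ] <-
        matrix(st$alpha[, p, ], n, Fk) * (matrix(dalpha[, p, ], n, Fk) - inner)
    de_mat <- matrix(de, n * Tp, Fk)
    # scoring network backward
    A_last <- st$acts[[L]]
    grads$Wao <- grads$Wao + crossprod(A_last, de_mat)
    grads$bao <- grads$bao + colSums(de_mat)
    dA <- de_mat %*% t(layer$params$Wao)
    for (l in rev(seq_len(L))) {
      dZl <- dA * (1 - st$acts[[l]]^2)
      A_in <- if (l == 1L) st$U else st$acts[[l - 1L]]
      grads[[paste0("Wa", l)]] <- grads[[paste0("Wa", l)]] + crossprod(A_in, dZl)
      grads[[paste0("ba", l)]] <- grads[[paste0("ba", l)]] + colSums(dZl)
      dA <- dZl %*% t(layer$params[[paste0("Wa", l)]])
    }
    dU <- dA  # [n*Tp, Fk + H]
    dX <- dX + array(dU[, seq_len(Fk)], c(n, Tp, Fk))
    dh_attn <- matrix(0, n, H)
    dUh <- array(dU[, Fk + seq_len(H)], c(n, Tp, H))
    for (p in seq_len(Tp)) dh_attn <- dh_attn + matrix(dUh[, p, ], n, H)
    dh_next <- dh_prev + dh_attn
  }
  list(dx = dX, grads = grads)
}

#' Build a Ra-SCNN model for a given input geometry
#'
#' @param cfg an [rascnn_config()].
#' @param T_len trial length in samples.
#' @param C number of channels.
#' @return an object of class `rascnn_model`.
#' @export
build_rascnn <- function(cfg, T_len, C) {
  fe_cfg <- cfg$front_end
  fe_cfg$seed <- cfg$seed
  fe <- build_scnn(fe_cfg, T_len, C)
  keep <- stage_idx(fe, c("spatial", "temporal"))
  layers <- fe$layers[keep]
  plan <- fe$plan
  seq_row <- if (fe_cfg$pool_width > 0L) plan[plan$stage == "pool", ]
             else plan[plan$stage == "temporal", ]
  Tp <- seq_row$time_len; Fk <- seq_row$kernels
  H <- cfg$hidden_units
  al <- layer_attn_lstm(Fk, H, cfg$attention_layers, cfg$use_full_sequence)
  # small uniform init for attention/recurrent weights
  al$params <- with_seed(cfg$seed + 7L, {
    for (nm in names(al$params)) {
      p <- al$params[[nm]]
      if (is.matrix(p)) {
        r <- sqrt(6 / (nrow(p) + ncol(p)))
        al$params[[nm]] <- matrix(stats::runif(length(p), -r, r), nrow(p), ncol(p))
      }
    }
    al$params
  })
  layers <- c(layers, list(al))
  n_in <- if (cfg$use_full_sequence) Tp * H else H
  for (w in cfg$dense_layers) {
    dl <- layer_dense(n_in, w, "head")
    layers <- c(layers, list(dl),
                list(layer_act(fe_cfg$activation, "head")))
    if (fe_cfg$batch_norm) layers <- c(layers, list(layer_bnorm(w, "head")))
    if (fe_cfg$dropout_rate > 0)
      layers <- c(layers, list(layer_dropout(fe_cfg$dropout_rate, FALSE, "head")))
    n_in <- w
  }
  layers <- c(layers, list(layer_dense(n_in, cfg$n_classes, "head")))
  # (re)initialize the dense additions
  head_new <- which(vapply(layers, function(l)
    l$stage == "head" && l$type == "dense", logical(1)))
  layers[head_new] <- with_seed(cfg$seed + 13L, {
    lapply(layers[head_new], function(l) {
      l$params$W <- matrix(stats::rnorm(length(l$params$W), 0,
                                        init_sd(nrow(l$params$W), fe_cfg$activation)),
                           nrow(l$params$W), ncol(l$params$W))
      l
    })
  })
  structure(list(type = "rascnn", cfg = cfg, input_shape = c(T_len, C),
                 layers = layers, seq_shape = c(Tp, Fk), classes = NULL),
            class = "rascnn_model")
}

rascnn_forward_full <- function(model, batch, training = FALSE) {
  batch <- check_batch(model, batch)
  d <- dim(batch)
  stack_forward(model$layers, array(batch, c(d, 1L)), training)
}

rascnn_backward_full <- function(model, fwd, dlogits) {
  stack_backward(fwd$layers, fwd$caches, dlogits)
}

#' Ra-SCNN forward pass (evaluation mode)
#'
#' @param model an `rascnn_model` from [build_rascnn()].
#' @param batch numeric array `n x T x C`.
#' @return logits matrix `n x n_classes`.
#' @export
rascnn_forward <- function(model, batch) {
  rascnn_forward_full(model, batch, training = FALSE)$out
}

#' @export
predict_proba.rascnn_model <- function(model, batch) {
  p <- softmax_rows(chunked_logits(model, batch, rascnn_forward))
  if (!is.null(model$classes)) colnames(p) <- model$classes
  p
}

rascnn_penultimate <- function(model, X) {
  nl <- length(model$layers)
  res <- stack_forward(model$layers, array(X, c(dim(X), 1L)), FALSE,
                       seq_len(nl - 1L))
  res$out
}
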