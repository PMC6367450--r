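test_that("attention weights are a stable softmax with unit row sums", {
  expect_equal(attention_weights(c(0, 0, 0, 0)), rep(0.25, 4))
  expect_equal(attention_weights(c(log(2), 0)), c(2/3, 1/3))
  e <- matrix(stats::rnorm(12, sd = 3), 3, 4)
  a <- attention_weights(e)
  expect_equal(rowSums(a), rep(1, 3))
  expect_true(all(a >= 0 & a <= 1))
  # max-subtraction keeps huge scores finite
  expect_equal(sum(attention_weights(c(1e4, 1e4))), 1)
  expect_error(attention_weights(c(1, NaN)), class = "megnet_contract_error")
})

test_that("attention application reduces to mean, selection, and weighted sums", {
  f <- matrix(c(1, 3, 5, 2, 4, 6), 3, 2)
  expect_equal(attention_apply(f, rep(1/3, 3)), colMeans(f))
  expect_equal(attention_apply(f, c(0, 1, 0)), f[2, ])
  expect_equal(attention_apply(matrix(c(1, 3), 2, 1), c(0.25, 0.75)), 2.5)
  expect_error(attention_apply(f, c(0.5, 0.5)), class = "megnet_contract_error")
})

make_tiny_rascnn <- function(use_full_sequence = FALSE, seed = 6) {
  fe <- scnn_config(list(c(3, 2)), temporal_filters = 3, temporal_kernel_taps = 2,
                    pool_width = 2, activation = "selu", n_classes = 2, seed = 5)
  cfg <- rascnn_config(fe, hidden_units = 4, attention_layers = 2,
                       use_full_sequence = use_full_sequence,
                       dense_layers = 5L, n_classes = 2, seed = seed)
  build_rascnn(cfg, 9, 3)
}

test_that("the Ra-SCNN produces [n x n_classes] logits", {
  model <- make_tiny_rascnn(use_full_sequence = TRUE)
  x <- array(stats::rnorm(4 * 9 * 3), c(4, 9, 3))
  expect_equal(dim(rascnn_forward(model, x)), c(4L, 2L))
})

test_that("zero scoring weights give uniform attention and a sequence-mean input", {
  model <- make_tiny_rascnn()
  li <- which(vapply(model$layers, function(l) l$type == "attn_lstm", logical(1)))
  al <- model$layers[[li]]
  for (nm in c("Wa1", "ba1", "Wa2", "ba2", "Wao", "bao"))
    al$params[[nm]][] <- 0
  feats <- array(stats::rnorm(2 * 4 * 3), c(2, 4, 3))
  fwd <- megnet:::fwd_attn_lstm(al, feats, training = FALSE)
  st <- fwd$cache$steps[[1]]
  expect_equal(st$alpha, array(1/4, c(2, 4, 3)))
  expect_equal(st$xin, apply(feats, c(1, 3), mean))
})

test_that("a length-one sequence makes attention a no-op", {
  al <- megnet:::layer_attn_lstm(3, 4, 1, FALSE)
  for (nm in names(al$params))
    if (is.matrix(al$params[[nm]]))
      al$params[[nm]][] <- stats::rnorm(length(al$params[[nm]]), sd = 0.3)
  feats <- array(stats::rnorm(2 * 1 * 3), c(2, 1, 3))
  fwd <- megnet:::fwd_attn_lstm(al, feats, training = FALSE)
  expect_equal(fwd$cache$steps[[1]]$alpha, array(1, c(2, 1, 3)))
  expect_equal(fwd$cache$steps[[1]]$xin, matrix(feats, 2, 3))
})

test_that("Ra-SCNN gradients (attention, LSTM, front end) match central differences", {
  set.seed(4)
  model <- make_tiny_rascnn(use_full_sequence = TRUE)
  x <- array(stats::rnorm(2 * 9 * 3), c(2, 9, 3))
  y <- diag(2)
  fwd <- megnet:::rascnn_forward_full(model, x, training = TRUE)
  loss <- megnet:::softmax_xent(fwd$out, y)
  bk <- megnet:::stack_backward(fwd$layers, fwd$caches, loss$dlogits)
  for (li in seq_along(model$layers)) {
    params <- model$layers[[li]]$params
    if (!length(params)) next
    for (nm in names(params)) {
      j <- sample(length(params[[nm]]), 1)
      g_num <- numeric_grad(function(d) {
        m2 <- model
        m2$layers[[li]]$params[[nm]][j] <- params[[nm]][j] + d
        megnet:::softmax_xent(megnet:::rascnn_forward_full(m2, x, TRUE)$out, y)$loss
      })
      expect_lt(abs(g_num - bk$grads[[li]][[nm]][j]), 1e-4)
    }
  }
})

test_that("the front end trains jointly: its gradients are non-zero after one step", {
  set.seed(9)
  model <- make_tiny_rascnn()
  x <- array(stats::rnorm(6 * 9 * 3), c(6, 9, 3))
  y <- matrix(0, 6, 2); y[cbind(1:6, rep(1:2, 3))] <- 1
  fwd <- megnet:::rascnn_forward_full(model, x, training = TRUE)
  loss <- megnet:::softmax_xent(fwd$out, y)
  bk <- megnet:::stack_backward(fwd$layers, fwd$caches, loss$dlogits)
  sp <- which(vapply(model$layers, function(l) l$type == "spatial_conv", logical(1)))
  tc <- which(vapply(model$layers, function(l) l$type == "temporal_conv", logical(1)))
  expect_gt(max(abs(bk$grads[[sp]]$W)), 0)
  expect_gt(max(abs(bk$grads[[tc]]$W)), 0)
})

test_that("a tiny Ra-SCNN fits an easy two-class problem", {
  # class A: strong positive mean on channel 1; class B: negative
  set.seed(12)
  n <- 24
  x <- array(stats::rnorm(n * 9 * 3, sd = 0.1), c(n, 9, 3))
  lab <- rep(c("A", "B"), each = n / 2)
  x[lab == "A", , 1] <- x[lab == "A", , 1] + 1
  x[lab == "B", , 1] <- x[lab == "B", , 1] - 1
  ts <- trial_set(x, lab, rep(sprintf("S%d", 1:4), each = 6),
                  rep("t1", n), 4L, 10)
  model <- make_tiny_rascnn()
  model$classes <- c("A", "B")
  tcfg <- train_config(learning_rate = 2e-2, batch_size = 12, epochs = 30, seed = 2)
  fit <- megnet:::fit_network(model, ts$data, match(lab, c("A", "B")), tcfg)
  expect_lt(utils::tail(fit$loss_history, 1), utils::head(fit$loss_history, 1))
  acc <- megnet:::model_accuracy(fit$model, ts$data, match(lab, c("A", "B")))
  expect_gte(acc, 0.9)
})

test_that("front-end configs with a dense head are rejected", {
  fe <- scnn_config(list(c(3, 2)), temporal_filters = 2, temporal_kernel_taps = 2,
                    dense_layers = 4L)
  expect_error(rascnn_config(fe, hidden_units = 4), class = "megnet_config_error")
})
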