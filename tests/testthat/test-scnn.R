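test_that("activation functions follow their standard definitions", {
  expect_equal(activation("selu", 0), 0)
  expect_equal(activation("selu", 1), 1.0507009873554805)
  expect_equal(activation("relu", -2.5), 0)
  expect_equal(activation("relu", 2.5), 2.5)
  expect_equal(activation("elu", -Inf), -1)
  expect_lt(abs(activation("selu", -1e9) - (-1.0507 * 1.6733)), 1e-3)
  expect_error(activation("tanh", 1), class = "megnet_config_error")
})

test_that("shape planning follows the channel-collapse arithmetic", {
  # two spatial layers: 151 channels -> 52 positions -> 1
  cfg <- scnn_config(list(c(100, 3), c(52, 5)), temporal_filters = 4,
                     temporal_kernel_taps = 11, pool_width = 4, n_classes = 2)
  plan <- plan_shapes(cfg, 400, 151)
  sp <- plan[plan$stage == "spatial_1", ]
  expect_equal(c(sp$time_len, sp$spatial_positions, sp$kernels), c(400, 52, 3))
  sp2 <- plan[plan$stage == "spatial_2", ]
  expect_equal(c(sp2$spatial_positions, sp2$kernels), c(1, 5))
  expect_equal(plan[plan$stage == "temporal", "time_len"], 390)
  expect_equal(plan[plan$stage == "pool", "time_len"], 97)  # floor(390 / 4)

  # single-layer collapse: taps = C
  cfg1 <- scnn_config(list(c(151, 7)), temporal_filters = 2,
                      temporal_kernel_taps = 3)
  plan1 <- plan_shapes(cfg1, 400, 151)
  expect_equal(plan1[plan1$stage == "spatial_1", "spatial_positions"], 1)

  # a non-collapsing stack is rejected, naming the layer
  bad <- scnn_config(list(c(100, 3)), temporal_filters = 2, temporal_kernel_taps = 3)
  expect_error(plan_shapes(bad, 400, 151), "layer 1",
               class = "megnet_config_error")
})

test_that("planned shapes and parameter counts match the realized model", {
  set.seed(101)
  for (rep in 1:20) {
    case <- random_scnn_case()
    plan <- plan_shapes(case$cfg, case$T_len, case$C)
    model <- build_scnn(case$cfg, case$T_len, case$C)
    expect_identical(count_params(model), as.integer(attr(plan, "n_params")))
    x <- array(stats::rnorm(3 * case$T_len * case$C), c(3, case$T_len, case$C))
    logits <- scnn_forward(model, x)
    expect_equal(dim(logits), c(3L, case$cfg$n_classes))
    sp_out <- megnet:::spatial_output(model, x)
    last_sp <- plan[grepl("^spatial", plan$stage), ]
    expect_equal(dim(sp_out), c(3L, case$T_len, last_sp$kernels[nrow(last_sp)]))
  }
})

test_that("an all-zero network emits identical logits for every input and class", {
  cfg <- tiny_scnn_cfg()
  model <- build_scnn(cfg, 50, 8)
  for (i in seq_along(model$layers))
    for (nm in names(model$layers[[i]]$params))
      model$layers[[i]]$params[[nm]][] <- 0
  x <- array(stats::rnorm(4 * 50 * 8), c(4, 50, 8))
  logits <- scnn_forward(model, x)
  expect_equal(max(abs(logits)), 0)
})

test_that("a one-layer linear toy reproduces the hand-computed spatial/temporal product", {
  # T = 3, C = 2; one spatial layer (2 taps -> collapse), identity
  # activation, normalization off, 1-tap temporal filter: the network is
  # logits = flatten(X %*% w_sp * w_t) %*% W_dense + b.
  cfg <- scnn_config(list(c(2, 1)), temporal_filters = 1,
                     temporal_kernel_taps = 1, pool_width = 0,
                     activation = "identity", batch_norm = FALSE,
                     n_classes = 2, seed = 3)
  model <- build_scnn(cfg, 3, 2)
  X <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2)   # columns are channels
  w_sp <- as.numeric(model$layers[[1]]$params$W)    # 2 taps
  w_t <- as.numeric(model$layers[[4]]$params$W)     # 1 tap
  Wd <- model$layers[[7]]$params$W; bd <- model$layers[[7]]$params$b
  by_hand <- as.numeric((X %*% w_sp) * w_t) %*% Wd + matrix(bd, 1, 2)
  got <- scnn_forward(model, array(X, c(1, 3, 2)))
  expect_equal(got, by_hand, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("with identity activation and no normalization the spatial stage is a time-shared linear map", {
  set.seed(7)
  cfg <- scnn_config(list(c(3, 3), c(4, 2)), temporal_filters = 2,
                     temporal_kernel_taps = 2, activation = "identity",
                     batch_norm = FALSE, n_classes = 2, seed = 9)
  C <- 6; T_len <- 5
  model <- build_scnn(cfg, T_len, C)
  # effective linear map: feed the channel-space identity basis
  basis <- array(0, c(C, T_len, C))
  for (c in seq_len(C)) basis[c, , c] <- 1
  eff <- megnet:::spatial_output(model, basis)[, 1L, ]   # C x S, row = input channel
  x <- array(stats::rnorm(2 * T_len * C), c(2, T_len, C))
  got <- megnet:::spatial_output(model, x)
  for (i in 1:2) {
    expected <- x[i, , ] %*% eff
    expect_equal(got[i, , ], expected, tolerance = 1e-10)
  }
})

test_that("permuting trials in a batch permutes logits identically", {
  cfg <- tiny_scnn_cfg()
  model <- build_scnn(cfg, 40, 8)
  x <- array(stats::rnorm(5 * 40 * 8), c(5, 40, 8))
  logits <- scnn_forward(model, x)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(scnn_forward(model, x[perm, , ]), logits[perm, ], tolerance = 1e-12)
})

test_that("backpropagated gradients match central differences for every layer type", {
  set.seed(11)
  cfg <- scnn_config(list(c(3, 3), c(2, 2)), temporal_filters = 2,
                     temporal_kernel_taps = 3, pool_width = 2,
                     activation = "selu", dense_layers = 5L,
                     n_classes = 2, seed = 2)
  model <- build_scnn(cfg, 10, 4)
  x <- array(stats::rnorm(2 * 10 * 4), c(2, 10, 4))
  y <- diag(2)
  fwd <- megnet:::scnn_forward_full(model, x, training = TRUE)
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
        megnet:::softmax_xent(megnet:::scnn_forward_full(m2, x, TRUE)$out, y)$loss
      })
      expect_lt(abs(g_num - bk$grads[[li]][[nm]][j]), 1e-5)
    }
  }
  # gradient with respect to the input (used by activation maximization)
  j <- 17L
  g_num <- numeric_grad(function(d) {
    x2 <- x; x2[j] <- x[j] + d
    megnet:::softmax_xent(megnet:::scnn_forward_full(model, x2, TRUE)$out, y)$loss
  })
  expect_lt(abs(g_num - bk$dx[j]), 1e-6)
})

test_that("evaluation-mode forward is deterministic under dropout configs", {
  cfg <- scnn_config(list(c(8, 4)), temporal_filters = 6, temporal_kernel_taps = 15,
                     pool_width = 10, dropout_rate = 0.5,
                     spatial_dropout_rate = 0.3, dense_layers = 8L,
                     n_classes = 2, seed = 21)
  model <- build_scnn(cfg, 50, 8)
  x <- array(stats::rnorm(3 * 50 * 8), c(3, 50, 8))
  expect_identical(scnn_forward(model, x), scnn_forward(model, x))
})

test_that("batch geometry mismatches raise contract errors", {
  model <- build_scnn(tiny_scnn_cfg(), 50, 8)
  expect_error(scnn_forward(model, array(0, c(2, 40, 8))),
               class = "megnet_contract_error")
  expect_error(scnn_forward(model, array(0, c(2, 50, 7))),
               class = "megnet_contract_error")
})
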