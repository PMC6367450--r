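test_that("greedy fold assignment balances trial totals deterministically", {
  counts <- c(a = 10, b = 8, c = 6, d = 4, e = 2)
  plan <- assign_folds(counts, 5)
  expect_equal(sort(plan$fold_totals), sort(c(10, 8, 6, 4, 2)))
  expect_equal(length(unique(plan$fold_of_subject)), 5L)

  counts2 <- stats::setNames(rep(5, 10), paste0("s", 1:10))
  plan2 <- assign_folds(counts2, 5)
  expect_equal(plan2$fold_totals, rep(10, 5))

  counts3 <- c(w = 9, x = 7, y = 5, z = 3)
  plan3 <- assign_folds(counts3, 2)
  expect_equal(sort(plan3$fold_totals), c(12, 12))
  expect_equal(unname(plan3$fold_of_subject[c("w", "z")]), c(1L, 1L))

  expect_error(assign_folds(counts3, 5), class = "megnet_validation_error")
})

test_that("test subjects are excluded from every fold (no leakage by construction)", {
  counts <- stats::setNames(sample(5:20, 12), paste0("s", 1:12))
  plan <- assign_folds(counts, 5, test_subjects = c("s3", "s7"))
  expect_false(any(c("s3", "s7") %in% names(plan$fold_of_subject)))
  expect_setequal(names(plan$fold_of_subject), setdiff(names(counts), c("s3", "s7")))
  # every non-test subject sits in exactly one fold
  expect_true(all(table(names(plan$fold_of_subject)) == 1L))
})

test_that("class weights follow 1 - n_class/n_total", {
  w <- class_weights(c(rep("A", 25), rep("B", 75)))
  expect_equal(unname(w[c("A", "B")]), c(0.75, 0.25))
  w2 <- class_weights(c(rep("x", 10), rep("y", 10)))
  expect_equal(unname(w2), c(0.5, 0.5))
  # a 38.13% majority class gets weight 0.6187
  counts <- as.table(c(maj = 3813, b = 3100, c = 3087))
  expect_equal(unname(class_weights(counts)["maj"]), 0.6187)
  expect_error(class_weights(character(0)), class = "megnet_validation_error")
})

test_that("neighbour label smoothing emits 0.6 interior / 0.8 boundary and sums to 1", {
  expect_equal(smooth_labels(4, 7), c(0, 0, 0.2, 0.6, 0.2, 0, 0))
  expect_equal(smooth_labels(1, 7), c(0.8, 0.2, 0, 0, 0, 0, 0))
  expect_equal(smooth_labels(7, 7), c(0, 0, 0, 0, 0, 0.2, 0.8))
  for (n in 2:8) for (k in seq_len(n))
    expect_equal(sum(smooth_labels(k, n)), 1)
  expect_error(smooth_labels(1, 1), class = "megnet_validation_error")
})

test_that("one-off accuracy counts immediate neighbours and dominates plain accuracy", {
  expect_equal(one_off_accuracy(1:5, 1:5), 1.0)
  expect_equal(one_off_accuracy(c(0, 3, 6), c(1, 5, 6)), 2 / 3)
  expect_equal(one_off_accuracy(c(1, 1), c(4, 5)), 0.0)
  set.seed(2)
  for (i in 1:20) {
    true <- sample(1:7, 30, replace = TRUE)
    pred <- sample(1:7, 30, replace = TRUE)
    expect_gte(one_off_accuracy(true, pred), mean(true == pred))
  }
  expect_error(one_off_accuracy(1:3, 1:4), class = "megnet_validation_error")
})

test_that("confusion matrices report per-actual-class rates", {
  cm <- confusion_matrix(c(1, 2, 3), c(1, 2, 3), 3)
  expect_equal(cm$rates, diag(3))
  cm2 <- confusion_matrix(c(1, 1), c(1, 2), 3)
  expect_equal(cm2$rates[1, ], c(0.5, 0.5, 0))
  expect_equal(cm2$empty_classes, c(2L, 3L))
  expect_equal(rowSums(cm2$counts), c(2, 0, 0))
  expect_error(confusion_matrix(c(1, 4), c(1, 1), 3), class = "megnet_validation_error")
})

test_that("class-weighted loss with equal classes is half the unweighted loss", {
  set.seed(3)
  logits <- matrix(stats::rnorm(20), 10, 2)
  targets <- matrix(0, 10, 2); targets[cbind(1:10, rep(1:2, 5))] <- 1
  plain <- megnet:::softmax_xent(logits, targets)$loss
  w <- rep(0.5, 10)  # 1 - n_c/n_total with two equal classes
  weighted <- megnet:::softmax_xent(logits, targets, w)$loss
  expect_equal(weighted, 0.5 * plain)
})

test_that("an untrained model scores at chance; a separable problem is fit to 100%", {
  spec <- small_band_spec(n_subjects = 6, trials_per_subject = 10, seed = 31)
  ts <- generate_trialset(spec)
  counts <- table(ts$subject_ids)
  plan <- assign_folds(stats::setNames(as.integer(counts), names(counts)),
                       2, test_subjects = c("S05", "S06"))
  # zero training epochs: held-out accuracy within 3 s.e. of chance
  res0 <- train_model(tiny_scnn_cfg(), ts, plan, train_config(epochs = 0L, seed = 5))
  n_test <- sum(ts$subject_ids %in% c("S05", "S06"))
  expect_lt(abs(res0$mean_test_acc - 0.5), 3 * sqrt(0.25 / n_test))

  # linearly separable two-class set: training accuracy reaches 1.0
  set.seed(8)
  n <- 40
  x <- array(stats::rnorm(n * 50 * 8, sd = 0.3), c(n, 50, 8))
  lab <- rep(c("A", "B"), each = n / 2)
  x[lab == "A", , 1] <- x[lab == "A", , 1] + 1
  x[lab == "B", , 1] <- x[lab == "B", , 1] - 1
  sep <- trial_set(x, lab, rep(sprintf("S%02d", 1:8), each = 5), rep("t1", n), 10L, 50)
  cnt <- table(sep$subject_ids)
  plan2 <- assign_folds(stats::setNames(as.integer(cnt), names(cnt)), 2)
  res <- train_model(tiny_scnn_cfg(), sep, plan2,
                     train_config(learning_rate = 5e-3, epochs = 20, seed = 6))
  expect_equal(res$folds[[1]]$train_acc, 1.0)
})

test_that("training with no class effect stays at chance on held-out subjects", {
  spec <- synth_spec(8, 10, 8, 100, 1, event_time = 0.25,
                     class_effects = list(
                       class_effect("A", c(8, 12), 0:3, 1),   # amplitude 1: no effect
                       class_effect("B", c(18, 22), 0:3, 1)),
                     seed = 77)
  ts <- generate_trialset(spec)
  counts <- table(ts$subject_ids)
  plan <- assign_folds(stats::setNames(as.integer(counts), names(counts)),
                       2, test_subjects = c("S07", "S08"))
  res <- train_model(tiny_scnn_cfg(), ts, plan,
                     train_config(learning_rate = 2e-3, epochs = 8, seed = 3))
  n_test <- sum(ts$subject_ids %in% c("S07", "S08"))
  expect_lt(abs(res$mean_test_acc - 0.5), 3 * sqrt(0.25 / n_test))
})

test_that("transfer evaluation freezes features and trains a linear max-margin head", {
  spec <- small_band_spec(seed = 55)
  ts <- generate_trialset(spec)
  model <- build_scnn(tiny_scnn_cfg(seed = 2), n_samples(ts), n_channels(ts))
  model$classes <- c("A", "B")
  # degenerate head: single-class training set predicts that class always
  one <- subset_trials(ts, ts$labels == "A" | ts$subject_ids == "S08")
  lab_backup <- one$labels
  one$labels[one$subject_ids != "S08"] <- "A"
  res_deg <- transfer_evaluate(model, one, "S08")
  expect_true(is.finite(res_deg$accuracy))
  one$labels <- lab_backup
  # frozen random features with a linear head beat the majority-class rate
  res_rand <- transfer_evaluate(model, ts, c("S07", "S08"))
  maj <- max(table(ts$labels[ts$subject_ids %in% c("S07", "S08")])) /
    sum(ts$subject_ids %in% c("S07", "S08"))
  expect_gte(res_rand$accuracy + 0.05, maj)
})

test_that("a trained frozen front end transfers at least as well as a random one", {
  spec <- small_band_spec(n_subjects = 8, trials_per_subject = 10,
                          amplitude = 4, seed = 91)
  ts <- generate_trialset(spec)
  counts <- table(ts$subject_ids)
  plan <- assign_folds(stats::setNames(as.integer(counts), names(counts)),
                       2, test_subjects = c("S07", "S08"))
  fit <- train_model(tiny_scnn_cfg(seed = 1), ts, plan,
                     train_config(learning_rate = 3e-3, epochs = 15, seed = 10))
  trained <- fit$folds[[which.max(vapply(fit$folds, `[[`, numeric(1), "val_acc"))]]$model
  # a fresh dataset from the same process plays the transfer task
  ts2 <- generate_trialset(small_band_spec(n_subjects = 6, trials_per_subject = 10,
                                           amplitude = 4, seed = 404))
  acc_trained <- transfer_evaluate(trained, ts2, c("S05", "S06"))$accuracy
  acc_random <- mean(vapply(1:5, function(s) {
    rnd <- build_scnn(tiny_scnn_cfg(seed = 100 + s), n_samples(ts2), n_channels(ts2))
    rnd$classes <- c("A", "B")
    transfer_evaluate(rnd, ts2, c("S05", "S06"))$accuracy
  }, numeric(1)))
  expect_gte(acc_trained + 1e-9, acc_random)
})

test_that("random hyperparameter search finds a near-optimal quadratic and logs every trial", {
  space <- list(x = list(type = "uniform", min = -5, max = 5))
  res <- hyper_search(space, function(cfg) (cfg$x - 2)^2, 100, seed = 7)
  expect_lt(abs(res$best$x - 2), 0.5)   # within 10% of the search range
  expect_equal(nrow(res$log), 100L)
  res1 <- hyper_search(space, function(cfg) cfg$x, 1, seed = 3)
  expect_equal(nrow(res1$log), 1L)
  expect_error(hyper_search(space, identity, 0), class = "megnet_validation_error")
})
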