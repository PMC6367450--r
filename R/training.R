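# Subject-wise cross-validation, losses, metrics, the training loop,
# transfer evaluation and a hyperparameter-search driver.

#' Subject-wise fold assignment
#'
#' Trials are split by *subject*: held-out test subjects appear in no
#' fold, and every non-test subject lands in exactly one fold, so no
#' subject's trials can leak between training, validation and test.
#' Subjects are ordered by trial count (descending) and assigned
#' greedily to the currently lightest fold, producing approximately
#' equal trial totals per fold. Ties break deterministically: equal
#' trial counts keep the input order of subjects, equal fold loads go to
#' the lowest fold index.
#'
#' @param trial_counts named integer vector: trials per subject.
#' @param n_folds number of cross-validation folds (>= 2).
#' @param test_subjects character vector of held-out subjects.
#' @return an object of class `fold_plan` with `fold_of_subject` (named
#'   integer), `test_subjects`, and `fold_totals`.
#' @export
assign_folds <- function(trial_counts, n_folds, test_subjects = character(0)) {
  if (n_folds < 2L) abort_validation("`n_folds` must be >= 2")
  if (is.null(names(trial_counts)))
    abort_validation("`trial_counts` must be named by subject")
  pool <- trial_counts[!(names(trial_counts) %in% test_subjects)]
  if (length(pool) < n_folds)
    abort_validation(sprintf("only %d non-test subjects for %d folds",
                             length(pool), n_folds))
  ord <- order(-as.numeric(pool))  # stable: ties keep input order
  totals <- rep(0, n_folds)
  fold_of <- integer(length(pool)); names(fold_of) <- names(pool)
  for (s in ord) {
    f <- which.min(totals)  # lowest index on ties
    fold_of[s] <- f
    totals[f] <- totals[f] + pool[s]
  }
  structure(list(n_folds = as.integer(n_folds),
                 fold_of_subject = fold_of,
                 test_subjects = as.character(test_subjects),
                 fold_totals = totals),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %d folds, totals: %s; %d test subject(s)\n",
              x$n_folds, paste(x$fold_totals, collapse = ", "),
              length(x$test_subjects)))
  invisible(x)
}

#' Class-imbalance loss weights
#'
#' Weight for class `c` is `1 - n_c / n_total`, so under-represented
#' classes are penalized more heavily when misclassified.
#'
#' @param labels vector of class labels (or a named table of counts).
#' @return named numeric vector of per-class weights.
#' @export
class_weights <- function(labels) {
  counts <- if (is.table(labels)) labels else table(labels)
  total <- sum(counts)
  if (total == 0) abort_validation("no labels supplied")
  w <- 1 - as.numeric(counts) / total
  names(w) <- names(counts)
  w
}

#' Ordinal neighbour label smoothing
#'
#' For ordered class targets, the one-hot label is replaced by a target
#' distribution placing 0.6 on the true class and 0.2 on each immediate
#' neighbour; at the two boundary classes the true class gets 0.8 and
#' its single neighbour 0.2. The distribution always sums to one.
#'
#' @param k 1-based index of the true class.
#' @param n_classes number of ordered classes (>= 2).
#' @return numeric probability vector of length `n_classes`.
#' @export
smooth_labels <- function(k, n_classes) {
  if (n_classes < 2L) abort_validation("`n_classes` must be >= 2")
  if (k < 1L || k > n_classes) abort_validation("`k` must be in 1..n_classes")
  out <- numeric(n_classes)
  if (k == 1L) {
    out[1L] <- 0.8; out[2L] <- 0.2
  } else if (k == n_classes) {
    out[n_classes] <- 0.8; out[n_classes - 1L] <- 0.2
  } else {
    out[k] <- 0.6; out[k - 1L] <- 0.2; out[k + 1L] <- 0.2
  }
  out
}

#' One-off accuracy for ordinal predictions
#'
#' Fraction of predictions landing on the true class or an immediately
#' neighbouring class (`|pred - true| <= 1` on the ordinal scale).
#'
#' @param true,pred equal-length integer vectors of ordinal class
#'   indices.
#' @return fraction in \[0, 1\].
#' @export
one_off_accuracy <- function(true, pred) {
  if (length(true) != length(pred))
    abort_validation("`true` and `pred` must have equal length")
  mean(abs(as.numeric(pred) - as.numeric(true)) <= 1)
}

#' Confusion matrix of per-class prediction rates
#'
#' @param true,pred integer class indices in `1..n_classes`.
#' @param n_classes number of classes.
#' @return list with `rates` (rows = actual class, each row summing to 1
#'   when the class has examples), `counts`, and `empty_classes` flagging
#'   classes with no examples (their rate rows are zero).
#' @export
confusion_matrix <- function(true, pred, n_classes) {
  if (any(true < 1L | true > n_classes) || any(pred < 1L | pred > n_classes))
    abort_validation("labels out of range 1..n_classes")
  counts <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(true))
    counts[true[i], pred[i]] <- counts[true[i], pred[i]] + 1L
  rs <- rowSums(counts)
  rates <- counts / ifelse(rs == 0, 1, rs)
  list(rates = rates, counts = counts, empty_classes = which(rs == 0))
}

#' Training configuration
#'
#' @param optimizer `"adam"` or `"sgd"`.
#' @param learning_rate positive step size.
#' @param batch_size minibatch size.
#' @param epochs number of passes over the training data.
#' @param class_weighting weight each example's loss by `1 - n_c/n_total`
#'   of its true class.
#' @param label_smoothing use the ordinal neighbour-smoothed target
#'   distribution instead of one-hot labels.
#' @param seed seed controlling shuffling, dropout and initialization
#'   offsets.
#' @param verbose print a per-epoch loss line to stderr.
#' @return an object of class `train_config`.
#' @export
train_config <- function(optimizer = "adam", learning_rate = 1e-3,
                         batch_size = 32L, epochs = 10L,
                         class_weighting = FALSE, label_smoothing = FALSE,
                         seed = 1L, verbose = FALSE) {
  if (!optimizer %in% c("adam", "sgd")) abort_config("optimizer must be 'adam' or 'sgd'")
  if (learning_rate <= 0 || batch_size < 1L || epochs < 0L)
    abort_config("rates and sizes must be positive")
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 class_weighting = isTRUE(class_weighting),
                 label_smoothing = isTRUE(label_smoothing),
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_config")
}

# Map labels to 1..K against a fixed class ordering.
encode_labels <- function(labels, classes) {
  idx <- match(as.character(labels), classes)
  if (anyNA(idx)) abort_contract("labels outside the model's class set")
  idx
}

target_matrix <- function(y_idx, n_classes, smoothing) {
  tg <- matrix(0, length(y_idx), n_classes)
  if (smoothing && n_classes >= 2L) {
    for (i in seq_along(y_idx)) tg[i, ] <- smooth_labels(y_idx[i], n_classes)
  } else {
    tg[cbind(seq_along(y_idx), y_idx)] <- 1
  }
  tg
}

model_forward_training <- function(model, xb, training) {
  if (model$type == "scnn") scnn_forward_full(model, xb, training)
  else rascnn_forward_full(model, xb, training)
}

model_backward_training <- function(model, fwd, dlogits) {
  if (model$type == "scnn") stack_backward(fwd$layers, fwd$caches, dlogits)
  else rascnn_backward_full(model, fwd, dlogits)
}

# Core minibatch loop shared by SCNN and Ra-SCNN. Aborts the fit with a
# diagnostic if the loss goes non-finite.
fit_network <- function(model, X, y_idx, tcfg, weights_by_class = NULL) {
  n <- dim(X)[1L]
  K <- model$cfg$n_classes
  targets <- target_matrix(y_idx, K, tcfg$label_smoothing)
  wts <- if (!is.null(weights_by_class)) weights_by_class[y_idx] else NULL
  state <- adam_init(model$layers)
  step <- 0L
  losses <- numeric(0)
  with_seed(tcfg$seed, {
    for (ep in seq_len(tcfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1L, n, by = tcfg$batch_size)) {
        idx <- ord[start:min(start + tcfg$batch_size - 1L, n)]
        xb <- X[idx, , , drop = FALSE]
        fwd <- model_forward_training(model, xb, training = TRUE)
        model$layers <- fwd$layers  # batch-norm running stats
        ls <- softmax_xent(fwd$out, targets[idx, , drop = FALSE],
                           if (is.null(wts)) NULL else wts[idx])
        if (!is.finite(ls$loss))
          stop_megnet(sprintf("non-finite loss at epoch %d; aborting fold", ep),
                      "megnet_numeric_error")
        bk <- model_backward_training(model, fwd, ls$dlogits)
        step <- step + 1L
        upd <- optim_step(model$layers, bk$grads, state,
                          lr = tcfg$learning_rate, t = step,
                          l2 = model$cfg$l2_penalty %||% 0,
                          optimizer = tcfg$optimizer)
        model$layers <- upd$layers
        state <- upd$state
        ep_loss <- ep_loss + ls$loss; nb <- nb + 1L
      }
      losses <- c(losses, ep_loss / max(nb, 1L))
      if (tcfg$verbose)
        message(sprintf("epoch %d/%d loss %.4f", ep, tcfg$epochs, ep_loss / max(nb, 1L)))
    }
  })
  list(model = model, loss_history = losses)
}

model_accuracy <- function(model, X, y_idx) {
  if (length(y_idx) == 0L) return(NA_real_)
  p <- predict_proba(model, X)
  mean(max.col(p, ties.method = "first") == y_idx)
}

#' Train a model with subject-wise cross-validation
#'
#' For each fold, a fresh model is trained on the trials of all other
#' folds and evaluated on (i) the fold's own subjects (validation) and
#' (ii) the held-out test subjects, who are never seen by any fold.
#' Subject leakage is impossible by construction of the
#' [fold_plan][assign_folds()]. Training is deterministic given the
#' seed (up to floating-point reduction order).
#'
#' @param model_cfg an [scnn_config()] or [rascnn_config()].
#' @param ts a [trial_set()] covering fold and test subjects.
#' @param fold_plan an [assign_folds()] plan.
#' @param tcfg a [train_config()].
#' @return an object of class `cv_result`: per-fold fitted models and
#'   metrics, plus `mean_val_acc` and `mean_test_acc`.
#' @export
train_model <- function(model_cfg, ts, fold_plan, tcfg) {
  classes <- sort(unique(as.character(ts$labels)))
  y_all <- encode_labels(ts$labels, classes)
  fold_of_trial <- fold_plan$fold_of_subject[ts$subject_ids]
  is_test <- ts$subject_ids %in% fold_plan$test_subjects
  if (any(is.na(fold_of_trial) & !is_test))
    abort_contract("trial subjects missing from the fold plan")
  wbc <- if (tcfg$class_weighting) {
    cw <- class_weights(factor(ts$labels[!is_test], levels = classes))
    as.numeric(cw)
  } else NULL
  Tlen <- n_samples(ts); C <- n_channels(ts)
  folds <- vector("list", fold_plan$n_folds)
  for (f in seq_len(fold_plan$n_folds)) {
    tr <- which(!is_test & fold_of_trial != f)
    va <- which(!is_test & fold_of_trial == f)
    te <- which(is_test)
    stopifnot(length(intersect(ts$subject_ids[tr], ts$subject_ids[va])) == 0L,
              length(intersect(ts$subject_ids[tr], ts$subject_ids[te])) == 0L)
    cfg_f <- model_cfg
    cfg_f$seed <- model_cfg$seed + f
    model <- if (inherits(model_cfg, "rascnn_config")) build_rascnn(cfg_f, Tlen, C)
             else build_scnn(cfg_f, Tlen, C)
    model$classes <- classes
    tcfg_f <- tcfg; tcfg_f$seed <- tcfg$seed + 1000L * f
    fit <- fit_network(model, ts$data[tr, , , drop = FALSE], y_all[tr],
                       tcfg_f, wbc)
    model <- fit$model
    folds[[f]] <- list(
      model = model,
      train_acc = model_accuracy(model, ts$data[tr, , , drop = FALSE], y_all[tr]),
      val_acc = model_accuracy(model, ts$data[va, , , drop = FALSE], y_all[va]),
      test_acc = model_accuracy(model, ts$data[te, , , drop = FALSE], y_all[te]),
      loss_history = fit$loss_history
    )
  }
  structure(list(folds = folds, classes = classes,
                 mean_val_acc = mean(vapply(folds, `[[`, numeric(1), "val_acc")),
                 mean_test_acc = mean(vapply(folds, `[[`, numeric(1), "test_acc"))),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds | mean val acc %.3f | mean held-out-subject acc %.3f\n",
              length(x$folds), x$mean_val_acc, x$mean_test_acc))
  invisible(x)
}

# Penultimate-stage features of a frozen model (evaluation mode): the
# input to the final classification layer.
frozen_features <- function(model, X) {
  if (model$type == "scnn") {
    nl <- length(model$layers)
    res <- stack_forward(model$layers, array(X, c(dim(X), 1L)), FALSE,
                         seq_len(nl - 1L))
    res$out
  } else {
    rascnn_penultimate(model, X)
  }
}

#' Transfer evaluation with a frozen feature extractor
#'
#' All model weights are fixed; the classification layer is discarded
#' and a linear max-margin classifier (SVM) is trained on the
#' penultimate-stage features of the training subjects, then scored on
#' the held-out subjects. This measures how well the learned features
#' carry over to a new task without any fine-tuning.
#'
#' @param model a fitted `scnn_model` or `rascnn_model`.
#' @param ts a [trial_set()] for the new task.
#' @param test_subjects subjects reserved for evaluation.
#' @return list with `accuracy` on held-out subjects, the fitted `head`,
#'   and the train/test trial counts.
#' @export
transfer_evaluate <- function(model, ts, test_subjects) {
  is_test <- ts$subject_ids %in% test_subjects
  if (!any(is_test)) abort_validation("no trials belong to `test_subjects`")
  if (all(is_test)) abort_validation("no training trials left outside `test_subjects`")
  feats <- frozen_features(model, ts$data)
  ytr <- factor(ts$labels[!is_test])
  yte <- as.character(ts$labels[is_test])
  Xtr <- feats[!is_test, , drop = FALSE]
  Xte <- feats[is_test, , drop = FALSE]
  if (nlevels(ytr) < 2L) {
    pred <- rep(levels(ytr)[1L], nrow(Xte))
    head_fit <- NULL
  } else {
    head_fit <- e1071::svm(Xtr, ytr, kernel = "linear", scale = FALSE)
    pred <- as.character(predict(head_fit, Xte))
  }
  list(accuracy = mean(pred == yte), head = head_fit,
       n_train = sum(!is_test), n_test = sum(is_test))
}

#' Random-search hyperparameter driver
#'
#' Seeded random search over a named space of dimensions; each dimension
#' is `list(type = "uniform"|"loguniform"|"int"|"choice", ...)` with
#' `min`/`max` bounds or a `values` vector. The driver is pluggable: any
#' sampler with the same contract (propose a config, receive its score)
#' can replace the built-in one; model-based samplers such as
#' tree-structured Parzen estimators slot in the same way when
#' available.
#'
#' @param space named list of dimension definitions.
#' @param objective function taking a named list of values, returning a
#'   numeric score to *minimize*.
#' @param n_iter number of evaluations (>= 1).
#' @param seed integer seed for the sampler.
#' @return list with `best` (config), `best_score`, and `log` (a data
#'   frame with one row per trial).
#' @export
hyper_search <- function(space, objective, n_iter, seed = 1L) {
  if (n_iter < 1L) abort_validation("`n_iter` must be >= 1")
  sample_dim <- function(d) {
    switch(d$type,
      uniform = stats::runif(1, d$min, d$max),
      loguniform = exp(stats::runif(1, log(d$min), log(d$max))),
      int = sample(seq.int(d$min, d$max), 1L),
      choice = d$values[[sample.int(length(d$values), 1L)]],
      abort_config(sprintf("unknown dimension type '%s'", d$type)))
  }
  with_seed(seed, {
    rows <- vector("list", n_iter)
    best <- NULL; best_score <- Inf
    for (i in seq_len(n_iter)) {
      cfg <- lapply(space, sample_dim)
      score <- objective(cfg)
      rows[[i]] <- data.frame(iter = i, score = score,
                              lapply(cfg, function(v) if (is.numeric(v)) v else as.character(v)))
      if (score < best_score) { best_score <- score; best <- cfg }
    }
    list(best = best, best_score = best_score, log = do.call(rbind, rows))
  })
}
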