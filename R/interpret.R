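# Model interrogation: activation maximization under a 1/f prior,
# channel topography maps, activation spectrograms, obscuring profiles
# and baseline-recording controls.

#' Configuration for regularized gradient ascent
#'
#' @param step_size ascent rate `eta` (> 0); 0.2 by default.
#' @param l2_theta L2 regularization weight `theta` (>= 0) on the
#'   generated input; 0.05 by default.
#' @param max_iters iteration cap (default 10000).
#' @param patience consecutive steps without objective improvement
#'   before stopping (default 5).
#' @param tol minimum improvement that counts as progress.
#' @param init `"one_over_f"` (zero-mean 1/f noise, the spectral prior
#'   of encephalographic background activity), `"zeros"`, or `"given"`
#'   (supply `init_value`).
#' @param init_value starting tensor when `init = "given"`.
#' @param spectral_exponent exponent of the 1/f init (and of the
#'   spectral-prior template).
#' @param spectral_lambda weight of the spectral-prior penalty
#'   `lambda * sum_k (a_k(x) - a0_k)^2`, where `a_k` is the amplitude
#'   spectrum of each column of `x` and `a0` the unit-variance 1/f
#'   template. 0 (default) disables it. Starting from 1/f noise alone
#'   does not stop the ascent from piling implausible power into a few
#'   bins far outside the regime the model was trained on; penalizing
#'   deviation from the expected spectrum keeps the generated input on
#'   the data manifold, where the model's class evidence is
#'   trustworthy.
#' @param seed seed for the random initialization.
#' @return an object of class `maximization_config`.
#' @export
maximization_config <- function(step_size = 0.2, l2_theta = 0.05,
                                max_iters = 10000L, patience = 5L,
                                tol = 1e-8, init = "one_over_f",
                                init_value = NULL, spectral_exponent = 1,
                                spectral_lambda = 0, seed = 1L) {
  if (step_size <= 0) abort_validation("`step_size` must be > 0")
  if (l2_theta < 0) abort_validation("`l2_theta` must be >= 0")
  if (patience < 1L) abort_validation("`patience` must be >= 1")
  if (!init %in% c("one_over_f", "zeros", "given"))
    abort_validation("`init` must be one_over_f, zeros or given")
  if (spectral_lambda < 0) abort_validation("`spectral_lambda` must be >= 0")
  structure(list(step_size = step_size, l2_theta = l2_theta,
                 max_iters = as.integer(max_iters), patience = as.integer(patience),
                 tol = tol, init = init, init_value = init_value,
                 spectral_exponent = spectral_exponent,
                 spectral_lambda = spectral_lambda, seed = as.integer(seed)),
            class = "maximization_config")
}

# Unit-variance 1/f^exponent amplitude-spectrum template over all T DFT
# bins (DC fixed at 0 for the zero-mean prior).
spectral_template <- function(Tlen, exponent) {
  nf <- floor(Tlen / 2)
  f <- seq_len(nf) / Tlen
  a <- numeric(Tlen)
  a[2:(nf + 1L)] <- f^(-exponent / 2)
  n_mirror <- if (Tlen %% 2 == 0) nf - 1L else nf
  if (n_mirror >= 1L)
    a[seq.int(Tlen, by = -1L, length.out = n_mirror)] <- a[seq.int(2L, length.out = n_mirror)]
  a / sqrt(sum(a^2))
}

# Value and gradient of lambda * sum_k (|X_k|/T - a0_k)^2 per column.
spectral_penalty <- function(x, a0, lambda) {
  d <- dim(x) %||% c(length(x), 1L)
  xm <- matrix(x, d[1L])
  Tlen <- nrow(xm)
  val <- 0
  grad <- xm * 0
  for (c in seq_len(ncol(xm))) {
    X <- stats::fft(xm[, c])
    amp <- Mod(X) / Tlen
    val <- val + sum((amp - a0)^2)
    w <- (amp - a0) / pmax(Mod(X), 1e-12)
    grad[, c] <- (2 / Tlen) * Re(stats::fft(w * X, inverse = TRUE))
  }
  list(value = lambda * val, grad = array(lambda * grad, d))
}

init_maximization <- function(shape, cfg) {
  switch(cfg$init,
    zeros = array(0, shape),
    given = {
      if (is.null(cfg$init_value)) abort_validation("init = 'given' needs `init_value`")
      array(cfg$init_value, shape)
    },
    one_over_f = with_seed(cfg$seed, {
      Tlen <- shape[1L]
      C <- if (length(shape) >= 2L) prod(shape[-1L]) else 1L
      if (Tlen >= 4L) {
        array(one_over_f_record(Tlen, C, cfg$spectral_exponent, 1), shape)
      } else {
        array(stats::rnorm(prod(shape)), shape)
      }
    })
  )
}

#' Activation maximization by regularized gradient ascent
#'
#' Synthesizes an input that maximizes a model output: starting from a
#' zero-mean 1/f-noise prior, the input is repeatedly moved along the
#' gradient of `f_o(x) - theta * sum(x^2)`, the gradient being
#' normalized by its RMS at every step to keep the ascent stable. The
#' ascent stops when the regularized objective fails to improve for
#' `patience` consecutive steps, or at `max_iters`. The returned
#' `x_gen` is the best iterate seen (the running arg max).
#'
#' @param objective function of the input tensor returning
#'   `list(value = , grad = )` with `grad` shaped like the input. See
#'   [objective_class_score()] for model-based objectives.
#' @param shape integer dimensions of the input to generate.
#' @param cfg a [maximization_config()].
#' @return an object of class `maximization_result`: `x_gen`, the
#'   per-iteration objective `trace`, and `stop_reason`
#'   (`"converged"` or `"max_iters"`).
#' @export
maximize_activation <- function(objective, shape, cfg = maximization_config()) {
  x <- init_maximization(shape, cfg)
  a0 <- if (cfg$spectral_lambda > 0)
    spectral_template(shape[1L], cfg$spectral_exponent) else NULL
  best_x <- x; best_obj <- -Inf
  trace <- numeric(0)
  stall <- 0L
  stop_reason <- "max_iters"
  for (it in seq_len(cfg$max_iters)) {
    ob <- objective(x)
    if (!is.finite(ob$value)) {
      warning("non-finite objective; aborting ascent with partial trace", call. = FALSE)
      stop_reason <- "non_finite"
      break
    }
    reg_obj <- ob$value - cfg$l2_theta * sum(x^2)
    g <- ob$grad - 2 * cfg$l2_theta * x
    if (!is.null(a0)) {
      sp <- spectral_penalty(x, a0, cfg$spectral_lambda)
      reg_obj <- reg_obj - sp$value
      g <- g - sp$grad
    }
    trace <- c(trace, reg_obj)
    if (reg_obj > best_obj + cfg$tol) {
      best_obj <- reg_obj; best_x <- x; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$patience) { stop_reason <- "converged"; break }
    }
    rms <- sqrt(mean(g^2))
    if (rms > 0) g <- g / rms
    x <- x + cfg$step_size * g
  }
  structure(list(x_gen = best_x, trace = trace, stop_reason = stop_reason),
            class = "maximization_result")
}

#' Model-based objectives for activation maximization
#'
#' Two input/output pairings are exposed, matching the two questions one
#' asks of a trained SCNN: `objective_spatial_component()` maximizes the
#' summed output of one kernel of the final spatial-summary layer with
#' respect to the *model input* (what channel mixture does this spatial
#' component prefer?); `objective_class_score()` maximizes the
#' log-probability of a class with respect to the *spatial-stage output
#' sequence* (what spatio-temporal feature time course drives this
#' class?). Both run the network in evaluation mode.
#'
#' @param model a fitted `scnn_model`.
#' @param component index of the spatial kernel to maximize.
#' @param class_idx index of the class (column of the logits).
#' @return a function suitable as the `objective` of
#'   [maximize_activation()]; its input shape is `c(T, C)` for
#'   `objective_spatial_component` and `c(T, S)` (spatial components
#'   over time) for `objective_class_score`.
#' @name maximization_objectives
NULL

#' @rdname maximization_objectives
#' @export
objective_spatial_component <- function(model, component) {
  idx <- stage_idx(model, "spatial")
  function(x) {
    d <- c(1L, dim(x))
    res <- stack_forward(model$layers, array(x, c(d, 1L)), FALSE, idx)
    out <- res$out  # [1, T, S]
    S <- dim(out)[3L]
    if (component < 1L || component > S)
      abort_contract(sprintf("component %d outside 1..%d", component, S))
    dout <- array(0, dim(out))
    dout[, , component] <- 1
    bk <- stack_backward(res$layers, res$caches, dout, idx)
    list(value = sum(out[, , component]), grad = array(bk$dx, dim(x)))
  }
}

#' @rdname maximization_objectives
#' @param contrast subtract the mean of the other class logits, so the
#'   ascent favours class-*discriminative* structure rather than
#'   features shared by all classes (default `TRUE`). The raw logit is
#'   used when `FALSE`. A softmax probability would saturate at 1 and
#'   stall the ascent, so the unsquashed output is maximized.
#' @export
objective_class_score <- function(model, class_idx, contrast = TRUE) {
  idx <- stage_idx(model, c("temporal", "head"))
  function(x) {
    res <- stack_forward(model$layers, array(x, c(1L, dim(x))), FALSE, idx)
    logits <- res$out
    K <- ncol(logits)
    if (class_idx < 1L || class_idx > K)
      abort_contract("class index outside the logits")
    dlogits <- matrix(0, 1L, K)
    if (contrast && K > 1L) {
      value <- logits[1L, class_idx] - mean(logits[1L, -class_idx])
      dlogits[1L, ] <- -1 / (K - 1)
      dlogits[1L, class_idx] <- 1
    } else {
      value <- logits[1L, class_idx]
      dlogits[1L, class_idx] <- 1
    }
    bk <- stack_backward(res$layers, res$caches, dlogits, idx)
    list(value = value, grad = array(bk$dx, dim(x)))
  }
}

#' Interpolated channel topography map
#'
#' Interpolates per-channel weights over a planar sensor layout onto a
#' regular grid, using local planar (barycentric-style) interpolation
#' from the three nearest channels, falling back to inverse-distance
#' weighting where the neighbourhood is degenerate (fewer than three
#' channels, or collinear ones). The map reproduces each channel's own
#' weight exactly at its coordinate.
#'
#' @param weights numeric vector of per-channel values (length `C`).
#' @param layout data frame with columns `x`, `y` (and optionally
#'   `channel`) giving planar coordinates for each of the `C` channels.
#' @param grid_n grid resolution per axis (default 64) or a list with
#'   `xlim`, `ylim`, `nx`, `ny`.
#' @return list with `z` (matrix `nx x ny`), `x`, `y` grid coordinates.
#' @export
topography_map <- function(weights, layout, grid_n = 64L) {
  C <- length(weights)
  if (nrow(layout) != C) abort_validation("`layout` must have one row per channel")
  px <- layout$x; py <- layout$y
  if (is.list(grid_n) && !is.null(grid_n$xlim)) {
    xs <- seq(grid_n$xlim[1L], grid_n$xlim[2L], length.out = grid_n$nx)
    ys <- seq(grid_n$ylim[1L], grid_n$ylim[2L], length.out = grid_n$ny)
  } else {
    xs <- seq(min(px), max(px), length.out = grid_n)
    ys <- seq(min(py), max(py), length.out = grid_n)
  }
  if (any(px < min(xs) | px > max(xs) | py < min(ys) | py > max(ys)))
    abort_validation("channel coordinate outside the interpolation grid")
  z <- matrix(NA_real_, length(xs), length(ys))
  for (i in seq_along(xs)) for (j in seq_along(ys)) {
    gx <- xs[i]; gy <- ys[j]
    d2 <- (px - gx)^2 + (py - gy)^2
    hit <- which(d2 < 1e-18)
    if (length(hit)) { z[i, j] <- weights[hit[1L]]; next }
    ord <- order(d2)
    val <- NA_real_
    if (C >= 3L) {
      k <- ord[1:3]
      A <- cbind(1, px[k], py[k])
      if (abs(det(A)) > 1e-10) {
        coefs <- solve(A, weights[k])
        val <- coefs[1L] + coefs[2L] * gx + coefs[3L] * gy
      }
    }
    if (is.na(val)) {
      w <- 1 / d2
      val <- sum(w * weights) / sum(w)
    }
    z[i, j] <- val
  }
  list(z = z, x = xs, y = ys)
}

#' Power spectral density spectrogram of an activation sequence
#'
#' Hann-tapered short-time power spectral density on a dB scale, the
#' standard view of what rhythm a generated or real activation carries
#' over time. Defaults: 64 FFT bins, 64-sample windows, 50 samples of
#' overlap between consecutive windows.
#'
#' @param x numeric vector (one activation sequence).
#' @param sampling_rate rate in Hz.
#' @param nfft FFT bins (and Hann window length unless `window_length`
#'   is given).
#' @param overlap samples of overlap between windows.
#' @param window_length Hann window length in samples.
#' @return list with `power_db` (matrix `frequency x frames`), `freq`
#'   (Hz), `time` (frame centres in s).
#' @export
activation_spectrogram <- function(x, sampling_rate, nfft = 64L,
                                   overlap = 50L, window_length = nfft) {
  if (length(x) < window_length)
    abort_validation(sprintf("sequence of %d samples is shorter than the %d-sample window",
                             length(x), window_length))
  if (overlap >= window_length) abort_validation("`overlap` must be < window length")
  w <- signal::hanning(window_length)
  hop <- window_length - overlap
  n_frames <- (length(x) - window_length) %/% hop + 1L
  nbin <- nfft %/% 2L + 1L
  P <- matrix(0, nbin, n_frames)
  U <- sampling_rate * sum(w^2)  # PSD normalization
  for (k in seq_len(n_frames)) {
    seg <- x[(k - 1L) * hop + seq_len(window_length)] * w
    sp <- stats::fft(c(seg, numeric(max(0L, nfft - window_length))))[seq_len(nbin)]
    P[, k] <- Mod(sp)^2 / U
  }
  list(power_db = 10 * log10(pmax(P, 1e-300)),
       freq = (seq_len(nbin) - 1L) * sampling_rate / nfft,
       time = ((seq_len(n_frames) - 1L) * hop + window_length / 2) / sampling_rate)
}

# Growth rates (pre, post) of the obscuring schedules, reduced so that
# e.g. an event at 0.5 s in a 3.5 s trial grows 6 post-event samples per
# pre-event sample.
obscure_rates <- function(Tlen, event_index) {
  pre <- event_index
  post <- Tlen - event_index
  if (pre <= 0L || post <= 0L)
    abort_validation("event index must leave samples on both sides of the event")
  g <- gcd2(pre, post)
  c(pre = pre / g, post = post / g)
}

# 0-based sample indices obscured after `step` growth steps.
obscure_indices <- function(Tlen, event_index, step, schedule) {
  r <- obscure_rates(Tlen, event_index)
  n_pre <- min(r["pre"] * step, event_index)
  n_post <- min(r["post"] * step, Tlen - event_index)
  if (schedule == "obscure_event") {
    pre_idx <- if (n_pre > 0) seq.int(event_index - n_pre, event_index - 1L) else integer(0)
    post_idx <- if (n_post > 0) seq.int(event_index, event_index + n_post - 1L) else integer(0)
  } else if (schedule == "obscure_ends") {
    pre_idx <- if (n_pre > 0) seq.int(0L, n_pre - 1L) else integer(0)
    post_idx <- if (n_post > 0) seq.int(Tlen - n_post, Tlen - 1L) else integer(0)
  } else {
    abort_validation("`schedule` must be 'obscure_event' or 'obscure_ends'")
  }
  list(pre = as.integer(pre_idx), post = as.integer(post_idx),
       all = as.integer(c(pre_idx, post_idx)), rates = r)
}

max_obscure_steps <- function(Tlen, event_index) {
  r <- obscure_rates(Tlen, event_index)
  min(event_index %/% r["pre"], (Tlen - event_index) %/% r["post"])
}

#' Obscure part of a trial with noise
#'
#' Replaces a growing portion of the trial with a 1:1000 weighted
#' mixture of signal and noise, `(signal + 1000 * noise) / 1001`, so
#' obscured samples are noise-dominated while unobscured samples are
#' untouched. `obscure_event` grows outward from the event onset and
#' `obscure_ends` inward from both ends, in both cases adding post-side
#' and pre-side samples in the ratio set by the trial's geometry (6
#' post-event samples per pre-event sample for an event at 0.5 s in a
#' 3.5 s trial). Uniform noise is scaled to each channel's standard
#' deviation.
#'
#' @param x trial matrix `T x C`.
#' @param event_index 0-based event-onset sample.
#' @param n_obscured total samples to obscure; taken from the growth
#'   ordering, so full growth steps honour the post:pre ratio exactly.
#' @param schedule `"obscure_event"` or `"obscure_ends"`.
#' @param noise optional `T x C` noise matrix; drawn uniformly per
#'   channel when omitted.
#' @param noise_weight relative noise weighting (default 1000).
#' @return the obscured trial matrix.
#' @export
obscure_trial <- function(x, event_index, n_obscured, schedule,
                          noise = NULL, noise_weight = 1000) {
  Tlen <- nrow(x)
  if (n_obscured < 0L || n_obscured > Tlen)
    abort_validation("`n_obscured` must be in 0..T")
  if (n_obscured == 0L) return(x)
  r <- obscure_rates(Tlen, event_index)
  per_step <- sum(r)
  full_steps <- n_obscured %/% per_step
  rem <- n_obscured - full_steps * per_step
  sel <- obscure_indices(Tlen, event_index, full_steps, schedule)$all
  if (rem > 0) {
    nxt <- obscure_indices(Tlen, event_index, full_steps + 1L, schedule)$all
    extra <- setdiff(nxt, sel)
    sel <- c(sel, extra[seq_len(min(rem, length(extra)))])
  }
  if (is.null(noise)) {
    sds <- apply(x, 2L, stats::sd)
    noise <- matrix(stats::runif(length(x), -sqrt(3), sqrt(3)), nrow(x)) %*% diag(sds, ncol(x))
  }
  out <- x
  out[sel + 1L, ] <- (x[sel + 1L, , drop = FALSE] +
                      noise_weight * noise[sel + 1L, , drop = FALSE]) / (1 + noise_weight)
  out
}

#' Obscuring profile of a trained model
#'
#' For each subject and task, the highest-confidence correctly
#' classified trial is selected; its correct-class output probability is
#' then recorded as the obscured portion grows step by step, for
#' `n_noise` independent noise draws per step. The profile's mean and
#' standard deviation across draws and trials show which part of the
#' trial the model's decision depends on: a model keyed to an
#' event-locked feature stays flat until the feature is obscured, then
#' declines.
#'
#' @param model a fitted model with a [predict_proba()] method.
#' @param ts a labelled [trial_set()] (typically held-out subjects).
#' @param schedule `"obscure_event"` or `"obscure_ends"`.
#' @param n_noise noise draws per step (default 10).
#' @param seed seed for the noise draws.
#' @return an object of class `obscuring_profile`: a data frame
#'   (`step`, `n_obscured`, `mean`, `sd`) plus the schedule, growth
#'   rates and selected trials.
#' @export
obscuring_profile <- function(model, ts, schedule, n_noise = 10L, seed = 1L) {
  probs <- predict_proba(model, ts$data)
  classes <- model$classes %||% sort(unique(as.character(ts$labels)))
  y_idx <- encode_labels(ts$labels, classes)
  pred <- max.col(probs, ties.method = "first")
  conf <- probs[cbind(seq_len(nrow(probs)), y_idx)]
  sel <- integer(0)
  for (s in unique(ts$subject_ids)) for (tk in unique(ts$task_ids)) {
    cand <- which(ts$subject_ids == s & ts$task_ids == tk & pred == y_idx)
    if (!length(cand)) {
      if (any(ts$subject_ids == s & ts$task_ids == tk))
        warning(sprintf("no correctly classified trial for subject %s / %s; skipped", s, tk),
                call. = FALSE)
      next
    }
    sel <- c(sel, cand[which.max(conf[cand])])
  }
  if (!length(sel)) abort_contract("no correctly classified trials to profile")
  Tlen <- n_samples(ts)
  ev <- ts$event_index[sel[1L]]
  if (is.na(ev)) abort_validation("profiled trials need an event index")
  n_steps <- max_obscure_steps(Tlen, ev)
  rates <- obscure_rates(Tlen, ev)
  means <- numeric(n_steps + 1L); sds <- numeric(n_steps + 1L)
  nobs <- integer(n_steps + 1L)
  with_seed(seed, {
    for (k in 0:n_steps) {
      vals <- numeric(0)
      for (i in sel) {
        x <- ts$data[i, , ]
        if (k == 0L) {
          vals <- c(vals, conf[i])  # clean trial: exact model output, no noise
          next
        }
        idxs <- obscure_indices(Tlen, ts$event_index[i], k, schedule)
        for (dr in seq_len(n_noise)) {
          xo <- obscure_trial(x, ts$event_index[i], length(idxs$all), schedule)
          p <- predict_proba(model, array(xo, c(1L, dim(xo))))
          vals <- c(vals, p[1L, y_idx[i]])
        }
      }
      means[k + 1L] <- mean(vals)
      sds[k + 1L] <- stats::sd(vals)
      nobs[k + 1L] <- if (k == 0L) 0L else length(obscure_indices(Tlen, ev, k, schedule)$all)
    }
  })
  structure(list(profile = data.frame(step = 0:n_steps, n_obscured = nobs,
                                      mean = means, sd = sds),
                 schedule = schedule, rates = rates, trials = sel),
            class = "obscuring_profile")
}

#' Least-squares slope of a profile segment
#'
#' @param step numeric step (or obscured-sample) coordinates.
#' @param mean_output mean model outputs at those steps.
#' @return list with `slope`, Pearson `r`, and the two-sided `p` value
#'   for a non-zero slope.
#' @export
fit_profile_slope <- function(step, mean_output) {
  if (length(step) < 3L || length(step) != length(mean_output))
    abort_validation("need at least 3 (step, mean) pairs")
  fit <- stats::lm(mean_output ~ step)
  sm <- suppressWarnings(summary(fit))  # perfect fits are fine here
  r <- suppressWarnings(stats::cor(step, mean_output))
  list(slope = unname(stats::coef(fit)[2L]),
       r = if (is.na(r)) 0 else r,
       p = if (nrow(sm$coefficients) > 1L) sm$coefficients[2L, 4L] else NA_real_)
}

#' Baseline-recording control
#'
#' Two control conditions probe whether a model's decisions rest on
#' event-related activity rather than resting-state characteristics:
#' (a) classify each subject's event-free baseline recording alone, and
#' (b) classify accurate test trials after subtracting the subject's
#' across-task mean baseline. A model keyed to event-locked structure
#' scores near chance on (a) but stays above chance on (b).
#'
#' @param model a fitted model with a [predict_proba()] method.
#' @param baselines a [trial_set()] of event-free recordings (one or
#'   more per subject; tasks averaged per subject for condition (b)).
#'   Baseline recordings must be at least as long as the model input;
#'   longer recordings use the leading model-length segment.
#' @param trials a labelled [trial_set()] of test trials.
#' @return list with the per-condition `counts` (correct/incorrect), the
#'   accuracies, and the evaluated trial indices.
#' @export
baseline_control <- function(model, baselines, trials) {
  Tm <- model$input_shape[1L]
  if (n_samples(baselines) < Tm)
    abort_validation(sprintf(
      "baseline recordings (%d samples) are shorter than the model input (%d); re-epoch them explicitly",
      n_samples(baselines), Tm))
  classes <- model$classes %||% sort(unique(as.character(trials$labels)))
  y_idx <- encode_labels(trials$labels, classes)
  seg <- baselines$data[, seq_len(Tm), , drop = FALSE]
  # condition (a): baseline segments alone, labelled by their subject's class
  yb <- encode_labels(baselines$labels, classes)
  pa <- predict_proba(model, seg)
  pred_a <- max.col(pa, ties.method = "first")
  # per-subject across-task mean baseline
  subj_mean <- list()
  for (s in unique(baselines$subject_ids)) {
    rows <- which(baselines$subject_ids == s)
    subj_mean[[s]] <- apply(seg[rows, , , drop = FALSE], c(2L, 3L), mean)
  }
  # condition (b): accurate, highly confident test trials minus the mean baseline
  probs <- predict_proba(model, trials$data)
  pred <- max.col(probs, ties.method = "first")
  conf <- probs[cbind(seq_len(nrow(probs)), y_idx)]
  sel <- integer(0)
  for (s in unique(trials$subject_ids)) for (tk in unique(trials$task_ids)) {
    if (!s %in% names(subj_mean)) {
      warning(sprintf("no baseline for subject %s; skipped", s), call. = FALSE)
      next
    }
    cand <- which(trials$subject_ids == s & trials$task_ids == tk & pred == y_idx)
    if (length(cand)) sel <- c(sel, cand[which.max(conf[cand])])
  }
  correct_b <- 0L; incorrect_b <- 0L
  for (i in sel) {
    x <- trials$data[i, seq_len(Tm), ] - subj_mean[[trials$subject_ids[i]]]
    p <- predict_proba(model, array(x, c(1L, Tm, n_channels(trials))))
    if (max.col(p, ties.method = "first") == y_idx[i]) correct_b <- correct_b + 1L
    else incorrect_b <- incorrect_b + 1L
  }
  counts <- data.frame(
    condition = c("initial_baseline_alone", "test_minus_average_baseline"),
    correct = c(sum(pred_a == yb), correct_b),
    incorrect = c(sum(pred_a != yb), incorrect_b)
  )
  list(counts = counts,
       accuracy = counts$correct / pmax(counts$correct + counts$incorrect, 1L),
       evaluated_trials = sel)
}
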