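quad_objective <- function(a) {
  function(x) list(value = -sum((x - a)^2), grad = -2 * (x - a))
}

test_that("regularized ascent reaches the closed-form optimum of a quadratic", {
  # theta = 0: maximum at a
  cfg0 <- maximization_config(step_size = 0.005, l2_theta = 0,
                              max_iters = 5000, init = "zeros")
  r0 <- maximize_activation(quad_objective(3), 1L, cfg0)
  expect_lt(abs(r0$x_gen - 3), 0.01)
  # theta = 0.05: the L2 penalty shrinks the optimum to a / (1 + theta)
  cfg1 <- maximization_config(step_size = 0.005, l2_theta = 0.05,
                              max_iters = 5000, init = "zeros")
  r1 <- maximize_activation(quad_objective(3), 1L, cfg1)
  expect_lt(abs(r1$x_gen - 3 / 1.05), 0.01)
})

test_that("a constant objective stops within the patience window at the init", {
  cfg <- maximization_config(step_size = 0.1, l2_theta = 0, patience = 5,
                             init = "zeros")
  r <- maximize_activation(function(x) list(value = 1, grad = x * 0), c(4, 2), cfg)
  expect_lte(length(r$trace), 6)   # patience + 1
  expect_equal(r$x_gen, array(0, c(4, 2)))
  expect_equal(r$stop_reason, "converged")
})

test_that("the objective trace is monotone non-decreasing for a stable step size", {
  cfg <- maximization_config(step_size = 0.01, l2_theta = 0.05,
                             max_iters = 300, init = "zeros")
  r <- maximize_activation(quad_objective(2), 1L, cfg)
  increments <- diff(r$trace[seq_len(which.max(r$trace))])
  expect_true(all(increments >= -1e-12))
})

test_that("the 1/f initialization has the prior's spectral shape and zero mean", {
  cfg <- maximization_config(init = "one_over_f", seed = 4)
  x <- megnet:::init_maximization(c(400, 4), cfg)
  expect_lt(abs(mean(x)), 0.05)
  P <- 0
  for (c in 1:4) P <- P + Mod(stats::fft(x[, c]))^2
  f <- (1:200) / 400
  sel <- 2:160
  slope <- stats::coef(stats::lm(log(P[sel]) ~ log(f[sel - 1])))[2]
  expect_lt(abs(slope + 1), 0.6)  # single realization: loose band around -1
})

test_that("topography interpolation honours channel values, constants, and midpoints", {
  layout3 <- data.frame(x = c(0, 1, 0.5), y = c(0, 0, 1))
  # one hot channel: the grid maximum sits at the node nearest that channel
  tm <- topography_map(c(1, 0, 0), layout3, grid_n = 21L)
  hot <- which(tm$z == max(tm$z), arr.ind = TRUE)[1, ]
  expect_lt(abs(tm$x[hot[1]] - 0), 0.06)
  expect_lt(abs(tm$y[hot[2]] - 0), 0.06)
  expect_equal(tm$z[1, 1], 1)   # the channel's own coordinate is exact
  # constant weights give a constant map
  tmc <- topography_map(c(2, 2, 2), layout3, grid_n = 11L)
  expect_lt(max(abs(tmc$z - 2)), 1e-9)
  # two channels: linear interpolation at the midpoint
  layout2 <- data.frame(x = c(0, 1), y = c(0, 0))
  tm2 <- topography_map(c(0, 2), layout2,
                        grid_n = list(xlim = c(0, 1), ylim = c(-0.1, 0.1), nx = 3, ny = 3))
  expect_equal(tm2$z[2, 2], 1.0)
  expect_error(topography_map(c(1, 2), data.frame(x = c(0, 5), y = c(0, 0)),
                              grid_n = list(xlim = c(0, 1), ylim = c(0, 1), nx = 3, ny = 3)),
               class = "megnet_validation_error")
})

test_that("spectrograms localize tones in the right bin with the right frame count", {
  fs <- 200
  x <- sin(2 * pi * 10 * (0:399) / fs)
  sg <- activation_spectrogram(x, fs)
  expect_equal(ncol(sg$power_db), 25L)   # floor((400 - 64)/14) + 1
  peak_bins <- apply(sg$power_db, 2L, which.max)
  expect_true(all(peak_bins == round(10 / (fs / 64)) + 1L))
  # DC input: all power in bin 0
  sgc <- activation_spectrogram(rep(1, 200), fs)
  expect_true(all(apply(sgc$power_db, 2L, which.max) == 1L))
  expect_error(activation_spectrogram(stats::rnorm(32), fs),
               class = "megnet_validation_error")
})

test_that("white-noise spectrogram power is flat across interior bins", {
  set.seed(5)
  acc <- 0
  for (i in 1:100) {
    sg <- activation_spectrogram(stats::rnorm(400), 200)
    acc <- acc + rowMeans(10^(sg$power_db / 10))
  }
  bins <- acc[2:32] / 100      # interior bins (DC and Nyquist scale differently)
  expect_lt(max(abs(bins - mean(bins))) / (stats::sd(bins) + 1e-12), 3.5)
  expect_lt(stats::sd(bins) / mean(bins), 0.15)
})

test_that("obscuring replaces samples at 1:1000 weighting with the 6:1 growth geometry", {
  set.seed(6)
  Tlen <- 700L; ev <- 100L   # event at 0.5 s of a 3.5 s trial at 200 Hz
  x <- matrix(stats::rnorm(Tlen * 2), Tlen, 2)
  expect_identical(obscure_trial(x, ev, 0L, "obscure_event"), x)
  # growth ratio: k steps obscure 6k post-event and k pre-event samples
  for (k in c(1L, 10L, 50L)) {
    idx <- megnet:::obscure_indices(Tlen, ev, k, "obscure_event")
    expect_length(idx$post, 6L * k)
    expect_length(idx$pre, k)
    expect_true(all(idx$post >= ev))
    expect_true(all(idx$pre < ev))
    ends <- megnet:::obscure_indices(Tlen, ev, k, "obscure_ends")
    expect_length(ends$post, 6L * k)
    expect_true(all(ends$post >= Tlen - 6L * k))
    expect_true(all(ends$pre < k))
  }
  # a fully obscured trial is noise-dominated: correlation with the original ~ 0
  cors <- vapply(1:10, function(i) {
    xr <- matrix(stats::rnorm(Tlen), Tlen, 1)
    stats::cor(obscure_trial(xr, ev, Tlen, "obscure_event")[, 1], xr[, 1])
  }, numeric(1))
  expect_lt(mean(abs(cors)), 0.05)
  expect_lt(max(abs(cors)), 0.15)
  # untouched samples are bit-identical
  ob <- obscure_trial(x, ev, 7L, "obscure_event")
  touched <- megnet:::obscure_indices(Tlen, ev, 1L, "obscure_event")$all + 1L
  expect_identical(ob[-touched, ], x[-touched, ])
})

test_that("profile slope regression recovers known lines", {
  s <- fit_profile_slope(0:10, 2 * (0:10) + 1)
  expect_equal(s$slope, 2)
  expect_equal(s$r, 1)
  expect_equal(fit_profile_slope(0:5, rep(3, 6))$slope, 0)
  set.seed(9)
  xs <- 0:99
  noisy <- -0.5 * xs + stats::rnorm(100, sd = 1)
  sn <- fit_profile_slope(xs, noisy)
  expect_lt(abs(sn$slope + 0.5), 0.05)
  expect_lt(sn$p, 1e-10)
  expect_error(fit_profile_slope(1:2, 1:2), class = "megnet_validation_error")
})

# Oracle model whose decision depends only on an event-locked window:
# mean of channel 1 over samples win (1-based), squashed to P(class A).
window_oracle <- function(Tlen, C, win, gain = 30) {
  custom_model(function(batch) {
    m <- apply(batch[, win, 1, drop = FALSE], 1L, mean)
    p <- 1 / (1 + exp(-gain * m))
    cbind(p, 1 - p)
  }, input_shape = c(Tlen, C), classes = c("A", "B"))
}

oracle_trialset <- function(n_per_class = 4, Tlen = 350L, C = 2, ev = 50L,
                            win = 151:250, seed = 21) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- array(stats::rnorm(n * Tlen * C, sd = 0.2), c(n, Tlen, C))
  lab <- rep(c("A", "B"), each = n_per_class)
  x[lab == "A", win, 1] <- x[lab == "A", win, 1] + 1
  x[lab == "B", win, 1] <- x[lab == "B", win, 1] - 1
  trial_set(x, lab, sprintf("S%02d", seq_len(n)), rep("t1", n), ev, 100)
}

test_that("an event-locked oracle yields a flat-then-declining obscure-event profile", {
  Tlen <- 350L; ev <- 50L; win <- 151:250
  ts <- oracle_trialset(Tlen = Tlen, ev = ev, win = win)
  model <- window_oracle(Tlen, 2, win)
  prof <- obscuring_profile(model, ts, "obscure_event", n_noise = 5, seed = 2)
  pr <- prof$profile
  # step 0 equals the clean-trial output exactly
  probs <- predict_proba(model, ts$data)
  y <- ifelse(ts$labels == "A", 1L, 2L)
  expect_equal(pr$mean[1], mean(probs[cbind(seq_len(nrow(probs)), y)]))
  # growth 6:1 from the event at 50/350: the window at samples 150..249
  # is first touched when 6k >= 101, i.e. k = 17
  flat <- pr$mean[pr$step <= 16]
  expect_lt(max(abs(flat - pr$mean[1])), 0.02)
  expect_lt(utils::tail(pr$mean, 1), pr$mean[1] - 0.2)
  # number of steps: pre side exhausts first at 1 + event_index / pre_rate
  expect_equal(nrow(pr), 1L + ev)
})

test_that("baseline controls separate event-locked decisions from resting activity", {
  Tlen <- 350L; ev <- 50L; win <- 151:250
  ts <- oracle_trialset(n_per_class = 10, Tlen = Tlen, ev = ev, win = win, seed = 33)
  model <- window_oracle(Tlen, 2, win)
  set.seed(44)
  bl_dat <- array(stats::rnorm(20 * Tlen * 2, sd = 0.2), c(20, Tlen, 2))
  baselines <- trial_set(bl_dat, ts$labels, ts$subject_ids, rep("t1", 20),
                         NA_integer_, 100)
  res <- baseline_control(model, baselines, ts)
  expect_equal(sum(res$counts[1, c("correct", "incorrect")]), 20)
  # (a) baselines carry no event-locked feature: accuracy ~ chance
  expect_lt(abs(res$accuracy[1] - 0.5), 3 * sqrt(0.25 / 20))
  # (b) trial minus average baseline keeps the feature: stays above chance
  expect_gt(res$accuracy[2], 0.8)
  short <- trial_set(bl_dat[, 1:100, , drop = FALSE], ts$labels, ts$subject_ids,
                     rep("t1", 20), NA_integer_, 100)
  expect_error(baseline_control(model, short, ts), class = "megnet_validation_error")
})
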