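# Shared fixtures and oracles, all generated in code.

# Small band-separated dataset: class A carries an 8-12 Hz effect,
# class B an 18-22 Hz effect, on the first few channels.
small_band_spec <- function(n_subjects = 8, trials_per_subject = 12,
                            n_channels = 8, fs = 100, duration = 1,
                            amplitude = 3, seed = 42) {
  synth_spec(n_subjects, trials_per_subject, n_channels, fs, duration,
             event_time = duration / 4,
             class_effects = list(
               class_effect("A", c(8, 12), 0:3, amplitude),
               class_effect("B", c(18, 22), 0:3, amplitude)),
             seed = seed)
}

tiny_scnn_cfg <- function(C = 8, activation = "relu", seed = 1,
                          n_classes = 2) {
  scnn_config(list(c(C, 4)), temporal_filters = 6, temporal_kernel_taps = 15,
              pool_width = 10, activation = activation,
              dense_layers = integer(0), l2_penalty = 1e-4,
              n_classes = n_classes, seed = seed)
}

# Central-difference gradient of a scalar function of one parameter entry.
numeric_grad <- function(f, eps = 1e-6) {
  (f(eps) - f(-eps)) / (2 * eps)
}

# Band power of one sequence by raw periodogram.
band_power <- function(v, fs, band) {
  n <- length(v)
  P <- Mod(stats::fft(v))^2 / n
  fr <- (seq_len(n) - 1) * fs / n
  sum(P[fr >= band[1] & fr <= band[2]])
}

# Brute-force circular autocorrelation (independent oracle for acf_fft).
acf_brute <- function(w) {
  n <- length(w)
  vapply(0:(n - 1), function(k) sum(w * w[((seq_len(n) - 1 + k) %% n) + 1]),
         numeric(1))
}

# Random valid SCNN configuration and input geometry for shape-plan
# property tests.
random_scnn_case <- function() {
  C <- sample(4:12, 1)
  n_layers <- sample(1:2, 1)
  if (n_layers == 2L) {
    t1 <- sample(2:(C - 1), 1)
    P <- C - t1 + 1
    taps <- if (P >= 2) c(t1, P) else NULL
    if (is.null(taps)) { n_layers <- 1L; taps <- C }
  } else {
    taps <- C
  }
  T_len <- sample(12:30, 1)
  tk <- sample(2:6, 1)
  pw <- sample(c(0, 2, 3), 1)
  cfg <- scnn_config(
    spatial_layers = lapply(seq_len(n_layers),
                            function(i) c(taps[i], sample(1:4, 1))),
    temporal_filters = sample(1:4, 1),
    temporal_kernel_taps = tk,
    pool_width = pw,
    activation = sample(c("relu", "elu", "selu"), 1),
    dense_layers = if (stats::runif(1) < 0.5) sample(2:6, 1) else integer(0),
    n_classes = sample(2:4, 1),
    seed = sample.int(1e6, 1))
  list(cfg = cfg, T_len = T_len, C = C)
}
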