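#' Specification for a synthetic trial dataset
#'
#' The generator emulates the statistical structure that single-trial
#' M/EEG decoders assume: a zero-mean background whose power spectrum
#' falls off as `1/f^exponent` (typical of encephalographic recordings),
#' and class-dependent band-limited oscillations concentrated in a subset
#' of channels. Per-subject multiplicative channel-gain jitter makes
#' subject-wise evaluation meaningfully harder than trial-wise
#' evaluation, mirroring the inter-subject variability of real sensor
#' data.
#'
#' A class effect is calibrated in terms of band power: an effect with
#' `amplitude = m` adds a sinusoid (frequency drawn uniformly within the
#' band per trial, random phase) whose expected power equals `(m - 1)`
#' times the background power inside that band, so that affected channels
#' carry `m` times the baseline band power. `amplitude = 1` therefore
#' means "no effect", which gives a clean knob for chance-level controls.
#'
#' @param n_subjects number of subjects.
#' @param trials_per_subject trials generated per subject.
#' @param n_channels number of channels `C`.
#' @param sampling_rate sampling rate in Hz.
#' @param trial_duration trial length in seconds.
#' @param event_time event (cue) onset in seconds, strictly inside the trial.
#' @param spectral_exponent background power is proportional to
#'   `1/f^spectral_exponent`; 1 by default.
#' @param class_effects list of effects built with [class_effect()].
#' @param label_rule either a character vector of length `n_subjects`
#'   mapping subject to class label, or `NULL` to assign the labels seen in
#'   `class_effects` round-robin over subjects.
#' @param noise_sd standard deviation of the background on every channel.
#' @param n_tasks number of task conditions cycled over a subject's trials.
#' @param subject_gain_jitter half-width of the per-subject, per-channel
#'   uniform gain jitter (0.1 means gains in \[0.9, 1.1\]).
#' @param seed integer seed; identical spec + seed reproduces identical data.
#'
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_subjects, trials_per_subject, n_channels,
                       sampling_rate, trial_duration,
                       event_time = trial_duration / 2,
                       spectral_exponent = 1,
                       class_effects = list(),
                       label_rule = NULL,
                       noise_sd = 1,
                       n_tasks = 1L,
                       subject_gain_jitter = 0.1,
                       seed = 1L) {
  spec <- structure(list(
    n_subjects = as.integer(n_subjects),
    trials_per_subject = as.integer(trials_per_subject),
    n_channels = as.integer(n_channels),
    sampling_rate = as.numeric(sampling_rate),
    trial_duration = as.numeric(trial_duration),
    event_time = as.numeric(event_time),
    spectral_exponent = as.numeric(spectral_exponent),
    class_effects = class_effects,
    label_rule = label_rule,
    noise_sd = as.numeric(noise_sd),
    n_tasks = as.integer(n_tasks),
    subject_gain_jitter = as.numeric(subject_gain_jitter),
    seed = as.integer(seed)
  ), class = "synth_spec")
  validate_synth_spec(spec)
  spec
}

#' Class-dependent band-limited effect
#'
#' @param label class label the effect belongs to.
#' @param band numeric length-2 frequency band in Hz.
#' @param channels 0-based channel indices carrying the effect.
#' @param amplitude band-power multiplier (> 0; 1 means no effect). See
#'   [synth_spec()] for the calibration.
#' @param post_event_only if `TRUE` the oscillation is present only from
#'   the event onset onward.
#' @return A list describing the effect.
#' @export
class_effect <- function(label, band, channels, amplitude,
                         post_event_only = FALSE) {
  list(label = as.character(label), band = as.numeric(band),
       channels = as.integer(channels), amplitude = as.numeric(amplitude),
       post_event_only = isTRUE(post_event_only))
}

validate_synth_spec <- function(spec) {
  for (f in c("n_subjects", "trials_per_subject", "n_channels"))
    if (is.na(spec[[f]]) || spec[[f]] < 1L)
      abort_validation(sprintf("`%s` must be a positive count", f))
  if (spec$sampling_rate <= 0) abort_validation("`sampling_rate` must be > 0")
  if (spec$trial_duration <= 0) abort_validation("`trial_duration` must be > 0")
  if (!(spec$event_time > 0 && spec$event_time < spec$trial_duration))
    abort_validation("`event_time` must satisfy 0 < event_time < trial_duration")
  if (spec$noise_sd <= 0) abort_validation("`noise_sd` must be > 0")
  if (spec$n_tasks < 1L) abort_validation("`n_tasks` must be a positive count")
  if (spec$subject_gain_jitter < 0 || spec$subject_gain_jitter >= 1)
    abort_validation("`subject_gain_jitter` must be in [0, 1)")
  for (i in seq_along(spec$class_effects)) {
    ef <- spec$class_effects[[i]]
    if (length(ef$band) != 2L || ef$band[1L] <= 0 || ef$band[2L] <= ef$band[1L])
      abort_validation(sprintf("`class_effects[[%d]]$band` must be an increasing pair of positive Hz", i))
    if (ef$band[2L] > spec$sampling_rate / 2)
      abort_validation(sprintf("`class_effects[[%d]]$band` exceeds the Nyquist frequency", i))
    if (any(ef$channels < 0L) || any(ef$channels >= spec$n_channels))
      abort_validation(sprintf("`class_effects[[%d]]$channels` must be 0-based indices < n_channels", i))
    if (is.na(ef$amplitude) || ef$amplitude <= 0)
      abort_validation(sprintf("`class_effects[[%d]]$amplitude` must be > 0", i))
    if (ef$amplitude < 1)
      abort_validation(sprintf("`class_effects[[%d]]$amplitude` below 1 would require negative band power", i))
  }
  if (!is.null(spec$label_rule) && !is.function(spec$label_rule) &&
      length(spec$label_rule) != spec$n_subjects)
    abort_validation("`label_rule` must be NULL, a function, or one label per subject")
  invisible(spec)
}

# Frequencies of the positive-frequency DFT bins for length-T records.
rfft_freqs <- function(Tlen, fs) {
  nf <- floor(Tlen / 2)
  (seq_len(nf)) * fs / Tlen
}

# One record of 1/f^exponent background: frequency-domain synthesis with
# deterministic amplitudes f^(-exponent/2) and uniform random phases,
# inverse transform, then exact standardization to sd = noise_sd.
one_over_f_record <- function(Tlen, C, exponent, noise_sd = 1) {
  freqs <- rfft_freqs(Tlen, fs = 1)  # shape only; fs cancels after scaling
  amp <- freqs^(-exponent / 2)
  nf <- length(freqs)
  spec <- matrix(0 + 0i, Tlen, C)
  phases <- matrix(stats::runif(nf * C, 0, 2 * pi), nf, C)
  pos <- amp * exp(1i * phases)
  if (Tlen %% 2 == 0) pos[nf, ] <- amp[nf] * cos(phases[nf, ])  # Nyquist bin must be real
  spec[2:(nf + 1L), ] <- pos
  # Hermitian symmetry for a real signal (the even-T Nyquist bin is its own mirror)
  n_mirror <- if (Tlen %% 2 == 0) nf - 1L else nf
  if (n_mirror >= 1L) {
    upper <- seq.int(Tlen, by = -1L, length.out = n_mirror)
    lower <- seq.int(2L, length.out = n_mirror)
    spec[upper, ] <- Conj(spec[lower, ])
  }
  x <- Re(stats::mvfft(spec, inverse = TRUE)) / Tlen
  x <- sweep(x, 2L, colMeans(x), "-")
  sds <- sqrt(colMeans(x^2))
  sds[sds == 0] <- 1
  sweep(x, 2L, noise_sd / sds, "*")
}

# Fraction of background power inside [band[1], band[2]] under the
# discrete 1/f^exponent synthesis spectrum.
band_power_fraction <- function(Tlen, fs, exponent, band) {
  freqs <- rfft_freqs(Tlen, fs)
  p <- freqs^(-exponent)
  sel <- freqs >= band[1L] & freqs <= band[2L]
  if (!any(sel)) abort_validation("effect band contains no DFT bin at this trial length")
  sum(p[sel]) / sum(p)
}

subject_labels <- function(spec) {
  if (is.function(spec$label_rule))
    return(vapply(seq_len(spec$n_subjects), spec$label_rule, character(1)))
  if (!is.null(spec$label_rule)) return(as.character(spec$label_rule))
  classes <- unique(vapply(spec$class_effects, `[[`, character(1), "label"))
  if (length(classes) == 0L) classes <- "A"
  classes[((seq_len(spec$n_subjects) - 1L) %% length(classes)) + 1L]
}

#' Generate a synthetic trial set
#'
#' Produces `n_subjects * trials_per_subject` trials of
#' `round(trial_duration * sampling_rate)` samples by `n_channels`
#' channels. Each trial is an independent 1/f^exponent background draw;
#' trials of a class with an effect additionally carry the calibrated
#' band-limited oscillation on the stated channels (restricted to
#' post-event samples when flagged). The whole dataset is a deterministic
#' function of the spec, including its seed.
#'
#' @param spec a [synth_spec()].
#' @return a [trial_set()].
#' @export
generate_trialset <- function(spec) {
  validate_synth_spec(spec)
  with_seed(spec$seed, generate_trialset_impl(spec))
}

generate_trialset_impl <- function(spec) {
  Tlen <- round(spec$trial_duration * spec$sampling_rate)
  C <- spec$n_channels
  fs <- spec$sampling_rate
  ev <- round(spec$event_time * fs)
  labels_by_subject <- subject_labels(spec)
  n <- spec$n_subjects * spec$trials_per_subject

  gains <- matrix(stats::runif(spec$n_subjects * C,
                               1 - spec$subject_gain_jitter,
                               1 + spec$subject_gain_jitter),
                  spec$n_subjects, C)

  # per-effect calibrated sinusoid amplitude
  eff_amp <- vapply(spec$class_effects, function(ef) {
    frac <- band_power_fraction(Tlen, fs, spec$spectral_exponent, ef$band)
    sqrt(2 * (ef$amplitude - 1) * frac) * spec$noise_sd
  }, numeric(1))

  dat <- array(0, c(n, Tlen, C))
  labels <- character(n); subj <- character(n); task <- character(n)
  tt <- (seq_len(Tlen) - 1L) / fs
  k <- 0L
  for (s in seq_len(spec$n_subjects)) {
    lab <- labels_by_subject[s]
    for (r in seq_len(spec$trials_per_subject)) {
      k <- k + 1L
      x <- one_over_f_record(Tlen, C, spec$spectral_exponent, spec$noise_sd)
      for (i in seq_along(spec$class_effects)) {
        ef <- spec$class_effects[[i]]
        if (ef$label != lab || eff_amp[i] == 0) next
        f0 <- stats::runif(1, ef$band[1L], ef$band[2L])
        ph <- stats::runif(1, 0, 2 * pi)
        wave <- eff_amp[i] * sin(2 * pi * f0 * tt + ph)
        if (ef$post_event_only) wave[seq_len(ev)] <- 0  # samples 0..ev-1 are pre-event
        x[, ef$channels + 1L] <- x[, ef$channels + 1L] + wave
      }
      x <- x * matrix(gains[s, ], Tlen, C, byrow = TRUE)
      dat[k, , ] <- x
      labels[k] <- lab
      subj[k] <- sprintf("S%02d", s)
      task[k] <- sprintf("task%d", ((r - 1L) %% spec$n_tasks) + 1L)
    }
  }
  trial_set(dat, labels, subj, task, event_index = ev, sampling_rate = fs)
}

#' Generate event-free baseline recordings
#'
#' One background-only recording per subject per task, with the same
#' channel count and sampling rate as the spec's trials and the
#' event-onset index marked absent. Baselines model the brief resting
#' recording collected before a subject's sequence of trials.
#'
#' @param spec a [synth_spec()].
#' @param duration recording length in seconds (> 0).
#' @return a [trial_set()] of `n_subjects * n_tasks` recordings with
#'   `event_index = NA`.
#' @export
generate_baselines <- function(spec, duration) {
  validate_synth_spec(spec)
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    abort_validation("`duration` must be a single positive number of seconds")
  # offset keeps baseline draws distinct from trial draws under one spec seed
  with_seed(spec$seed + 104729L, {
    Tlen <- round(duration * spec$sampling_rate)
    C <- spec$n_channels
    n <- spec$n_subjects * spec$n_tasks
    dat <- array(0, c(n, Tlen, C))
    subj <- character(n); task <- character(n)
    labels_by_subject <- subject_labels(spec)
    labels <- character(n)
    gains <- matrix(stats::runif(spec$n_subjects * C,
                                 1 - spec$subject_gain_jitter,
                                 1 + spec$subject_gain_jitter),
                    spec$n_subjects, C)
    k <- 0L
    for (s in seq_len(spec$n_subjects)) {
      for (tk in seq_len(spec$n_tasks)) {
        k <- k + 1L
        x <- one_over_f_record(Tlen, C, spec$spectral_exponent, spec$noise_sd)
        dat[k, , ] <- x * matrix(gains[s, ], Tlen, C, byrow = TRUE)
        subj[k] <- sprintf("S%02d", s)
        task[k] <- sprintf("task%d", tk)
        labels[k] <- labels_by_subject[s]
      }
    }
    trial_set(dat, labels, subj, task, event_index = NA_integer_,
              sampling_rate = spec$sampling_rate)
  })
}
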