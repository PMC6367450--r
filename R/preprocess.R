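# Minimal preprocessing: resample, zero-phase band-pass, epoching and
# cropped-trial augmentation. The pipeline order used throughout the
# package is fixed: resample -> band-pass -> epoch -> (optional) crop.

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

# small rational approximation p/q ~= x
rat_approx <- function(x, max_den = 4096L) {
  best <- c(round(x), 1L); err <- abs(x - best[1L])
  for (q in seq_len(max_den)) {
    p <- round(x * q)
    e <- abs(x - p / q)
    if (e < err - 1e-15) { best <- c(p, q); err <- e }
    if (err < 1e-12) break
  }
  best
}

# Rational-rate resampling of one vector: zero-stuff by p, zero-phase
# Butterworth anti-aliasing (exactly unit DC gain), take every q-th
# sample. The caller handles edge padding.
resample_1d <- function(v, p, q, n_out) {
  if (p > 1L) {
    up <- numeric(length(v) * p)
    up[seq(1L, by = p, length.out = length(v))] <- v * p
  } else up <- v
  cutoff <- min(1 / p, 1 / q)
  if (cutoff < 1) {
    filt <- signal::butter(6, 0.9 * cutoff, type = "low")
    up <- signal::filtfilt(filt, up)
  }
  up[seq(1L, by = q, length.out = n_out)]
}

#' Resample a trial set to a new rate
#'
#' Rational-rate resampling of every channel of every trial: the signal
#' is upsampled by zero-stuffing where needed, low-pass filtered with a
#' zero-phase Butterworth anti-aliasing filter, and decimated; edges
#' are reflection-padded so filter transients fall outside the trial.
#' The event-onset index is rescaled by the same ratio. Upsampling is
#' refused unless explicitly allowed, since it adds no information and
#' silently inflates the data.
#'
#' @param ts a [trial_set()].
#' @param target_rate new sampling rate in Hz.
#' @param allow_upsample permit `target_rate > ts$sampling_rate`.
#' @return a resampled `trial_set` with `T' = round(T * target/original)`.
#' @export
resample_trialset <- function(ts, target_rate, allow_upsample = FALSE) {
  if (!is.numeric(target_rate) || length(target_rate) != 1L || target_rate <= 0)
    abort_validation("`target_rate` must be a single positive rate in Hz")
  if (target_rate > ts$sampling_rate && !allow_upsample)
    abort_validation("refusing to upsample; pass allow_upsample = TRUE to force")
  ratio <- target_rate / ts$sampling_rate
  if (abs(ratio - 1) < 1e-12) return(ts)
  pq <- rat_approx(ratio)
  p <- pq[1L]; q <- pq[2L]
  g <- gcd2(p, q); p <- p / g; q <- q / g
  Tlen <- n_samples(ts)
  newT <- round(Tlen * ratio)
  n <- n_trials(ts); C <- n_channels(ts)
  # reflect-pad both ends (a whole number of q-sample blocks) so the
  # polyphase filter's edge transients fall outside the kept segment
  pad <- q * max(0L, min(25L, (Tlen - 1L) %/% q))
  trim <- pad * p / q
  out <- array(0, c(n, newT, C))
  for (i in seq_len(n)) for (c in seq_len(C)) {
    v <- ts$data[i, , c]
    vp <- if (pad > 0) c(v[(pad + 1L):2L], v, v[(Tlen - 1L):(Tlen - pad)]) else v
    y <- resample_1d(vp, p, q, n_out = trim + newT)
    out[i, , c] <- y[trim + seq_len(newT)]
  }
  ei <- ifelse(is.na(ts$event_index), NA_integer_,
               as.integer(round(ts$event_index * ratio)))
  trial_set(out, ts$labels, ts$subject_ids, ts$task_ids, ei, target_rate)
}

#' Zero-phase band-pass filter
#'
#' Butterworth band-pass applied forward-backward ([signal::filtfilt()])
#' so the filter has zero phase and no group delay: event-onset indices
#' stay valid. When `high` reaches the Nyquist frequency the filter
#' degenerates to a high-pass at `low`.
#'
#' @param ts a [trial_set()].
#' @param low lower pass-band edge in Hz (> 0).
#' @param high upper pass-band edge in Hz (<= Nyquist).
#' @param order Butterworth prototype order per edge (default 4).
#' @return a filtered `trial_set` with identical geometry.
#' @export
bandpass_trialset <- function(ts, low, high, order = 4L) {
  nyq <- ts$sampling_rate / 2
  if (!(low > 0 && high > low)) abort_validation("need 0 < low < high")
  if (high > nyq) abort_validation(sprintf("`high` = %g Hz exceeds Nyquist (%g Hz)", high, nyq))
  filt <- if (high >= 0.999 * nyq) {
    signal::butter(order, low / nyq, type = "high")
  } else {
    signal::butter(order, c(low, high) / nyq, type = "pass")
  }
  n <- n_trials(ts); C <- n_channels(ts)
  out <- ts$data
  for (i in seq_len(n)) for (c in seq_len(C))
    out[i, , c] <- signal::filtfilt(filt, ts$data[i, , c])
  trial_set(out, ts$labels, ts$subject_ids, ts$task_ids, ts$event_index,
            ts$sampling_rate)
}

#' Epoch a continuous recording around cue onsets
#'
#' Cuts fixed-length trials from a continuous `T x C` recording,
#' `pre` seconds before to `post` seconds after each cue. Cues too close
#' to a recording edge are skipped with a warning rather than crashing,
#' so a handful of unusable cues does not abort a session.
#'
#' @param x numeric matrix `T x C`, one continuous recording.
#' @param sampling_rate sampling rate of `x` in Hz.
#' @param cue_times cue onsets in seconds from the start of the recording.
#' @param pre seconds kept before each cue (>= 0).
#' @param post seconds kept after each cue (> 0).
#' @param labels,subject_id,task_id metadata attached to the resulting
#'   trials; `labels` may be one value per cue.
#' @return a [trial_set()] with `T = round((pre + post) * rate)` samples
#'   per trial and `event_index = round(pre * rate)`.
#' @export
epoch_recording <- function(x, sampling_rate, cue_times, pre, post,
                            labels = NA_character_, subject_id = "S01",
                            task_id = "task1") {
  if (!is.matrix(x)) abort_validation("`x` must be a T x C matrix")
  if (pre < 0 || post <= 0) abort_validation("need pre >= 0 and post > 0")
  Tlen <- round((pre + post) * sampling_rate)
  ev <- round(pre * sampling_rate)
  N <- nrow(x); C <- ncol(x)
  if (length(labels) == 1L) labels <- rep(labels, length(cue_times))
  keep <- list(); keep_lab <- character(0)
  for (j in seq_along(cue_times)) {
    start <- round(cue_times[j] * sampling_rate) - ev  # 0-based start sample
    if (start < 0L || start + Tlen > N) {
      warning(sprintf("cue %d at t = %g s too close to a recording edge; skipped",
                      j, cue_times[j]), call. = FALSE)
      next
    }
    keep[[length(keep) + 1L]] <- x[start + seq_len(Tlen), , drop = FALSE]
    keep_lab <- c(keep_lab, labels[j])
  }
  nkeep <- length(keep)
  dat <- array(0, c(nkeep, Tlen, C))
  for (i in seq_len(nkeep)) dat[i, , ] <- keep[[i]]
  trial_set(dat, keep_lab, rep(subject_id, nkeep), rep(task_id, nkeep),
            event_index = ev, sampling_rate = sampling_rate)
}

#' Cropping plan for trial augmentation
#'
#' @param window_length crop length in seconds.
#' @param stride step between crop start offsets, in samples (>= 1).
#' @param require_event keep only crops containing the event onset.
#' @return an object of class `crop_plan`.
#' @export
crop_plan <- function(window_length, stride = 1L, require_event = TRUE) {
  if (window_length <= 0) abort_validation("`window_length` must be > 0 seconds")
  if (stride < 1L) abort_validation("`stride` must be >= 1 sample")
  structure(list(window_length = as.numeric(window_length),
                 stride = as.integer(stride),
                 require_event = isTRUE(require_event)),
            class = "crop_plan")
}

# All candidate start offsets for a trial of T samples and window W at
# the given stride. The count at stride 1 is exactly T - W (offsets
# 0 .. T-W-1); window == trial yields the single identity crop.
crop_offsets <- function(Tlen, W, stride) {
  if (W == Tlen) return(0L)
  seq.int(0L, Tlen - W - 1L, by = stride)
}

#' Cropped-trial augmentation
#'
#' Multiplies the number of training examples by sliding a window shorter
#' than the trial across each trial and keeping every (optionally
#' event-containing) placement as a new fixed-length trial. At stride 1
#' a trial of duration `d` seconds yields `(d - window_length) * rate`
#' crops; for 3.5 s trials, a 2 s window and 200 Hz this is the 300:1
#' augmentation used with cropped training. Every crop is an exact
#' contiguous slice of its source trial; the event index is re-expressed
#' relative to each crop and labels/subject/task are replicated.
#'
#' A crop starting at offset `s` (0-based) contains the event at index
#' `e` iff `s <= e < s + W` (half-open convention).
#'
#' @param ts a [trial_set()].
#' @param plan a [crop_plan()].
#' @return an augmented `trial_set` of window-length trials.
#' @export
crop_augment <- function(ts, plan) {
  W <- round(plan$window_length * ts$sampling_rate)
  Tlen <- n_samples(ts)
  if (W > Tlen) abort_validation("`window_length` exceeds the trial duration")
  offs <- crop_offsets(Tlen, W, plan$stride)
  n <- n_trials(ts); C <- n_channels(ts)
  pieces_idx <- vector("list", n)
  for (i in seq_len(n)) {
    oi <- offs
    if (plan$require_event) {
      e <- ts$event_index[i]
      if (is.na(e))
        abort_validation(sprintf("require_event set but trial %d has no event index", i))
      oi <- oi[oi <= e & e < oi + W]
      if (length(oi) == 0L)
        abort_validation(sprintf("no crop offset can contain the event of trial %d", i))
    }
    pieces_idx[[i]] <- oi
  }
  total <- sum(lengths(pieces_idx))
  dat <- array(0, c(total, W, C))
  labels <- rep(ts$labels[1L], total); subj <- character(total)
  task <- character(total); ev <- integer(total)
  k <- 0L
  for (i in seq_len(n)) {
    for (s in pieces_idx[[i]]) {
      k <- k + 1L
      dat[k, , ] <- ts$data[i, s + seq_len(W), ]
      labels[k] <- ts$labels[i]
      subj[k] <- ts$subject_ids[i]
      task[k] <- ts$task_ids[i]
      e <- ts$event_index[i]
      # events falling outside a (non-event-required) crop are marked absent
      ev[k] <- if (is.na(e) || e < s || e >= s + W) NA_integer_ else e - s
    }
  }
  trial_set(dat, labels, subj, task, ev, ts$sampling_rate)
}
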