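#' Trial container for multichannel electrophysiology
#'
#' A `trial_set` holds a stack of fixed-length trials as a numeric array of
#' dimension `n_trials x T x C` (trials, samples, channels), together with
#' per-trial labels, subject and task identifiers, the sample index of the
#' event (cue) onset, and the sampling rate. It is the common currency of
#' every stage in the package: the synthetic generator produces one,
#' preprocessing transforms one, and models consume one.
#'
#' Sample indices, including `event_index`, are 0-based offsets from the
#' start of a trial (the first sample has index 0), so that the cropping
#' and obscuring arithmetic can be stated without off-by-one adjustments.
#' `event_index` may be `NA` for event-free recordings such as baselines.
#'
#' @param data numeric array `n_trials x T x C`.
#' @param labels per-trial class labels (length `n_trials`).
#' @param subject_ids per-trial subject identifiers.
#' @param task_ids per-trial task identifiers.
#' @param event_index integer vector of 0-based event-onset sample indices
#'   (`NA` where absent). A scalar is recycled.
#' @param sampling_rate sampling rate in Hz.
#'
#' @return An object of class `trial_set`.
#' @export
trial_set <- function(data, labels, subject_ids, task_ids,
                      event_index = NA_integer_, sampling_rate) {
  if (!is.array(data) || length(dim(data)) != 3L)
    abort_validation("`data` must be a 3-d array [n_trials x T x C]")
  n <- dim(data)[1L]
  if (length(labels) != n)
    abort_validation(sprintf("`labels` has length %d, expected %d", length(labels), n))
  if (length(subject_ids) != n)
    abort_validation(sprintf("`subject_ids` has length %d, expected %d", length(subject_ids), n))
  if (length(task_ids) != n)
    abort_validation(sprintf("`task_ids` has length %d, expected %d", length(task_ids), n))
  if (length(event_index) == 1L) event_index <- rep(as.integer(event_index), n)
  if (length(event_index) != n)
    abort_validation(sprintf("`event_index` has length %d, expected %d", length(event_index), n))
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L || sampling_rate <= 0)
    abort_validation("`sampling_rate` must be a single positive number")
  Tlen <- dim(data)[2L]
  ei <- as.integer(event_index)
  bad <- which(!is.na(ei) & (ei < 0L | ei >= Tlen))
  if (length(bad))
    abort_validation(sprintf("`event_index` out of range [0, T) for trial(s) %s",
                             paste(utils::head(bad, 5L), collapse = ", ")))
  structure(list(
    data = data,
    labels = labels,
    subject_ids = as.character(subject_ids),
    task_ids = as.character(task_ids),
    event_index = ei,
    sampling_rate = as.numeric(sampling_rate)
  ), class = "trial_set")
}

#' Number of trials in a trial set
#' @param ts a `trial_set`.
#' @return integer count.
#' @export
n_trials <- function(ts) dim(ts$data)[1L]

#' Trial length in samples
#' @param ts a `trial_set`.
#' @return integer count.
#' @export
n_samples <- function(ts) dim(ts$data)[2L]

#' Number of channels
#' @param ts a `trial_set`.
#' @return integer count.
#' @export
n_channels <- function(ts) dim(ts$data)[3L]

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> %d trials x %d samples x %d channels @ %g Hz\n",
              n_trials(x), n_samples(x), n_channels(x), x$sampling_rate))
  cat(sprintf("  subjects: %d  tasks: %d  classes: %s\n",
              length(unique(x$subject_ids)), length(unique(x$task_ids)),
              paste(sort(unique(as.character(x$labels))), collapse = ", ")))
  ev <- unique(x$event_index)
  cat(sprintf("  event_index: %s\n",
              if (all(is.na(ev))) "absent" else paste(utils::head(ev, 4L), collapse = ", ")))
  invisible(x)
}

#' Subset trials of a trial set
#'
#' @param ts a `trial_set`.
#' @param idx integer or logical index over trials.
#' @return a `trial_set` with the selected trials.
#' @export
subset_trials <- function(ts, idx) {
  trial_set(ts$data[idx, , , drop = FALSE], ts$labels[idx],
            ts$subject_ids[idx], ts$task_ids[idx],
            ts$event_index[idx], ts$sampling_rate)
}

#' Combine trial sets with identical geometry
#'
#' @param ... `trial_set` objects sharing `T`, `C` and sampling rate.
#' @return a single concatenated `trial_set`.
#' @export
bind_trials <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1L]]) && !inherits(parts[[1L]], "trial_set"))
    parts <- parts[[1L]]
  stopifnot(length(parts) >= 1L)
  Tlen <- n_samples(parts[[1L]]); C <- n_channels(parts[[1L]])
  fs <- parts[[1L]]$sampling_rate
  for (p in parts)
    if (n_samples(p) != Tlen || n_channels(p) != C || p$sampling_rate != fs)
      abort_contract("trial sets to bind must share T, C and sampling_rate")
  dat <- do.call(abind3, lapply(parts, function(p) p$data))
  trial_set(dat,
            unlist(lapply(parts, function(p) p$labels), use.names = FALSE),
            unlist(lapply(parts, function(p) p$subject_ids), use.names = FALSE),
            unlist(lapply(parts, function(p) p$task_ids), use.names = FALSE),
            unlist(lapply(parts, function(p) p$event_index), use.names = FALSE),
            fs)
}

# rbind for 3-d arrays along the first margin
abind3 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1L]])
  ntot <- sum(vapply(arrs, function(a) dim(a)[1L], integer(1)))
  out <- array(0, c(ntot, d[2L], d[3L]))
  at <- 0L
  for (a in arrs) {
    na <- dim(a)[1L]
    if (na > 0L) out[at + seq_len(na), , ] <- a
    at <- at + na
  }
  out
}

SCHEMA_VERSION <- "1.0"

#' Save a trial set as an array file plus JSON manifest
#'
#' The container is a directory with two files: `data.bin`, the trial
#' tensor written as IEEE little-endian doubles in R's column-major order
#' over dimensions `[n_trials, T, C]`, and `manifest.json` describing the
#' shapes, sampling rate, metadata vectors and an MD5 checksum of the
#' array file. The round trip through [load_trialset()] is lossless.
#'
#' @param ts a `trial_set`.
#' @param path directory to create/write into.
#' @return Invisibly, the manifest as a list.
#' @export
save_trialset <- function(ts, path) {
  if (!inherits(ts, "trial_set")) abort_contract("`ts` must be a trial_set")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  datafile <- file.path(path, "data.bin")
  con <- file(datafile, "wb")
  writeBin(as.vector(ts$data), con, size = 8L, endian = "little")
  close(con)
  manifest <- list(
    schema_version = SCHEMA_VERSION,
    n_trials = n_trials(ts), n_samples = n_samples(ts), n_channels = n_channels(ts),
    sampling_rate = ts$sampling_rate,
    labels = as.character(ts$labels),
    subject_ids = ts$subject_ids,
    task_ids = ts$task_ids,
    event_index = ts$event_index,
    md5 = unname(tools::md5sum(datafile))
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(manifest)
}

#' Load a trial set saved by [save_trialset()]
#'
#' @param path container directory.
#' @return a `trial_set`.
#' @export
load_trialset <- function(path) {
  mf <- file.path(path, "manifest.json")
  df <- file.path(path, "data.bin")
  if (!file.exists(mf)) abort_format(sprintf("missing manifest: %s", mf))
  manifest <- tryCatch(jsonlite::read_json(mf, simplifyVector = TRUE),
                       error = function(e) abort_format(sprintf("corrupt manifest: %s", conditionMessage(e))))
  need <- c("n_trials", "n_samples", "n_channels", "sampling_rate")
  if (!all(need %in% names(manifest)))
    abort_format("manifest is missing required shape fields")
  if (!file.exists(df)) abort_format(sprintf("missing array file: %s", df))
  n <- manifest$n_trials; Tlen <- manifest$n_samples; C <- manifest$n_channels
  expected <- as.numeric(n) * Tlen * C
  nbytes <- file.info(df)$size
  if (nbytes != expected * 8)
    abort_integrity(sprintf("array file holds %g values but manifest declares %g",
                            nbytes / 8, expected))
  con <- file(df, "rb")
  vals <- readBin(con, "double", n = expected, size = 8L, endian = "little")
  close(con)
  ei <- manifest$event_index
  if (is.null(ei) || length(ei) == 0L) ei <- rep(NA_integer_, n)
  ei[is.na(ei)] <- NA_integer_
  labels <- manifest$labels %||% rep(NA_character_, n)
  if (n == 0L) {
    labels <- character(0); ei <- integer(0)
    manifest$subject_ids <- character(0); manifest$task_ids <- character(0)
  }
  trial_set(array(vals, c(n, Tlen, C)), labels,
            manifest$subject_ids, manifest$task_ids, ei, manifest$sampling_rate)
}
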