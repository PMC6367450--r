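# The comparison feature-engineering pipeline: short rectangular
# windows, per-window spectral/statistical features, FFT-based circular
# autocorrelation, and correlation-based feature selection.

#' Windowing plan for feature extraction
#'
#' Rectangular windows of `window_ms` with `overlap_ms` of overlap; a
#' 2000 ms epoch at 50 ms / 25 ms gives 79 windows.
#'
#' @param window_ms window length in milliseconds.
#' @param overlap_ms overlap between consecutive windows (0 <= overlap
#'   < window).
#' @return an object of class `window_plan`.
#' @export
window_plan <- function(window_ms = 50, overlap_ms = 25) {
  if (!(overlap_ms >= 0 && overlap_ms < window_ms))
    abort_validation("need 0 <= overlap_ms < window_ms")
  structure(list(window_ms = window_ms, overlap_ms = overlap_ms),
            class = "window_plan")
}

#' Window start/end samples for an epoch
#'
#' @param epoch_ms epoch length in milliseconds (>= window length).
#' @param plan a [window_plan()].
#' @param sampling_rate rate in Hz used to convert to sample indices.
#' @return data frame of 0-based `start` and exclusive `end` sample
#'   indices; `floor((epoch - window)/hop) + 1` windows.
#' @export
plan_windows <- function(epoch_ms, plan, sampling_rate = 200) {
  if (epoch_ms < plan$window_ms)
    abort_validation("epoch is shorter than the window")
  hop_ms <- plan$window_ms - plan$overlap_ms
  n_win <- floor((epoch_ms - plan$window_ms) / hop_ms) + 1L
  start_ms <- (seq_len(n_win) - 1L) * hop_ms
  start <- round(start_ms * sampling_rate / 1000)
  wlen <- round(plan$window_ms * sampling_rate / 1000)
  data.frame(window = seq_len(n_win), start = start, end = start + wlen)
}

#' Circular autocorrelation via the FFT
#'
#' `ACF(w) = iFFT(|FFT(w)|^2)`: the circular autocorrelation sequence of
#' the window (Wiener-Khinchin). The result is real up to numerical
#' noise; the real part is returned.
#'
#' @param w numeric window (non-empty).
#' @return numeric vector of the same length; lag `k` at position
#'   `k + 1`.
#' @export
acf_fft <- function(w) {
  if (!length(w)) abort_validation("`w` must be non-empty")
  Re(stats::fft(Mod(stats::fft(w))^2, inverse = TRUE)) / length(w)
}

# Levinson-Durbin recursion on the (biased) autocorrelation sequence;
# returns `order` LPC coefficients (prediction polynomial, sign
# convention x_t ~ sum a_k x_{t-k}).
lpc_coefficients <- function(w, order = 4L) {
  n <- length(w)
  if (n <= order) return(rep(0, order))
  r <- vapply(0:order, function(k) sum(w[seq_len(n - k)] * w[(1L + k):n]) / n,
              numeric(1))
  if (r[1L] <= 0) return(rep(0, order))
  a <- numeric(order); e <- r[1L]
  for (k in seq_len(order)) {
    acc <- r[k + 1L]
    if (k > 1L) acc <- acc - sum(a[seq_len(k - 1L)] * r[k:2L])
    refl <- acc / e
    a_new <- a
    a_new[k] <- refl
    if (k > 1L) a_new[seq_len(k - 1L)] <- a[seq_len(k - 1L)] - refl * a[(k - 1L):1L]
    a <- a_new
    e <- e * (1 - refl^2)
    if (e <= 0) break
  }
  a
}

scalar_feature_kinds <- c("mean", "abs_mean", "quad_mean", "nz_mean",
                          "nz_abs_mean", "nz_quad_mean", "variance",
                          "skewness", "kurtosis", "rms", "log_energy")

#' Per-window summary and spectral features
#'
#' Standard openSMILE-style window descriptors: plain/absolute/quadratic
#' means (also over non-zero samples only), variance, skewness,
#' kurtosis, RMS, the log of the signal energy, short-FFT magnitude
#' bins, linear-predictive-coding coefficients and the circular
#' autocorrelation sequence. Skewness and kurtosis of a constant window
#' are reported as 0 with a warning (their moment ratios are
#' undefined), so constant segments do not poison a feature table with
#' NaN.
#'
#' @param w numeric window (non-empty).
#' @param kinds character vector of feature kinds; any of `"mean"`,
#'   `"abs_mean"`, `"quad_mean"`, `"nz_mean"`, `"nz_abs_mean"`,
#'   `"nz_quad_mean"`, `"variance"`, `"skewness"`, `"kurtosis"`,
#'   `"rms"`, `"log_energy"`, `"fft"`, `"lpc"`, `"acf"`.
#' @param fft_points FFT length for the `"fft"` kind (the window is
#'   truncated, or zero-padded if shorter).
#' @param lpc_order LPC order for the `"lpc"` kind.
#' @return named numeric vector of feature values.
#' @export
window_features <- function(w, kinds, fft_points = 8L, lpc_order = 4L) {
  if (!length(w)) abort_validation("`w` must be non-empty")
  if (!length(kinds)) abort_validation("at least one feature kind is required")
  unknown <- setdiff(kinds, c(scalar_feature_kinds, "fft", "lpc", "acf"))
  if (length(unknown))
    abort_validation(sprintf("unknown feature kind(s): %s", paste(unknown, collapse = ", ")))
  out <- numeric(0)
  nz <- w[w != 0]
  for (kind in kinds) {
    v <- switch(kind,
      mean = mean(w),
      abs_mean = mean(abs(w)),
      quad_mean = sqrt(mean(w^2)),
      nz_mean = if (length(nz)) mean(nz) else 0,
      nz_abs_mean = if (length(nz)) mean(abs(nz)) else 0,
      nz_quad_mean = if (length(nz)) sqrt(mean(nz^2)) else 0,
      variance = mean((w - mean(w))^2),
      skewness = {
        s <- stats::sd(w)
        if (is.na(s) || s == 0) { warning("skewness of a constant window set to 0", call. = FALSE); 0 }
        else e1071::skewness(w)
      },
      kurtosis = {
        s <- stats::sd(w)
        if (is.na(s) || s == 0) { warning("kurtosis of a constant window set to 0", call. = FALSE); 0 }
        else e1071::kurtosis(w)
      },
      rms = sqrt(mean(w^2)),
      log_energy = log(max(sum(w^2), 1e-300)),
      fft = {
        seg <- if (length(w) >= fft_points) w[seq_len(fft_points)]
               else c(w, numeric(fft_points - length(w)))
        m <- Mod(stats::fft(seg))[seq_len(fft_points %/% 2L + 1L)]
        names(m) <- sprintf("fft_mag_%d", seq_along(m) - 1L)
        m
      },
      lpc = {
        a <- lpc_coefficients(w, lpc_order)
        names(a) <- sprintf("lpc_%d", seq_len(lpc_order))
        a
      },
      acf = {
        a <- acf_fft(w)
        names(a) <- sprintf("acf_%d", seq_along(a) - 1L)
        a
      })
    if (is.null(names(v)) || kind %in% scalar_feature_kinds) names(v) <- kind
    out <- c(out, v)
  }
  out
}

#' Assemble a trial-by-feature table
#'
#' Applies an optional channel-mixing transform (for example a matrix of
#' statistically independent components obtained elsewhere; identity by
#' default), cuts each component into the planned windows, computes the
#' requested feature kinds per window, and concatenates everything into
#' one row per trial with systematic `comp{c}_win{w}_{kind}` names.
#'
#' @param ts a [trial_set()].
#' @param plan a [window_plan()].
#' @param kinds feature kinds, as in [window_features()].
#' @param mixing optional `C x n_components` mixing matrix (identity by
#'   default); components are `trial %*% mixing`.
#' @param fft_points,lpc_order passed to [window_features()].
#' @return a numeric matrix `n_trials x n_features` of class
#'   `feature_table` with feature names as column names and extraction
#'   provenance in `attr(, "provenance")`.
#' @export
assemble_features <- function(ts, plan, kinds, mixing = NULL,
                              fft_points = 8L, lpc_order = 4L) {
  if (!length(kinds)) abort_validation("at least one feature kind is required")
  C <- n_channels(ts)
  if (is.null(mixing)) mixing <- diag(C)
  if (nrow(mixing) != C) abort_validation("`mixing` must have one row per channel")
  epoch_ms <- n_samples(ts) / ts$sampling_rate * 1000
  wins <- plan_windows(epoch_ms, plan, ts$sampling_rate)
  n <- n_trials(ts)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    comps <- ts$data[i, , ] %*% mixing
    vals <- numeric(0)
    for (cc in seq_len(ncol(comps))) {
      for (wi in seq_len(nrow(wins))) {
        seg <- comps[(wins$start[wi] + 1L):wins$end[wi], cc]
        fv <- window_features(seg, kinds, fft_points, lpc_order)
        names(fv) <- sprintf("comp%d_win%d_%s", cc, wi, names(fv))
        vals <- c(vals, fv)
      }
    }
    rows[[i]] <- vals
  }
  X <- do.call(rbind, rows)
  if (anyNA(X) || any(!is.finite(X))) {
    warning("non-finite feature values imputed to 0", call. = FALSE)
    X[!is.finite(X)] <- 0
  }
  structure(X, class = c("feature_table", class(X)),
            provenance = list(kinds = kinds, window_ms = plan$window_ms,
                              overlap_ms = plan$overlap_ms,
                              n_components = ncol(mixing),
                              fft_points = fft_points, lpc_order = lpc_order))
}

#' Correlation-based feature selection rule
#'
#' @param alpha significance level applied after Bonferroni correction
#'   over the number of features.
#' @param r_min minimum absolute Pearson correlation.
#' @return an object of class `selection_rule`.
#' @export
selection_rule <- function(alpha = 1e-5, r_min = 0.2) {
  if (!(alpha > 0 && alpha < 1)) abort_validation("`alpha` must be in (0, 1)")
  if (!(r_min >= 0 && r_min < 1)) abort_validation("`r_min` must be in [0, 1)")
  structure(list(alpha = alpha, r_min = r_min, correction = "bonferroni"),
            class = "selection_rule")
}

#' Select features correlated with a target
#'
#' Pearson correlation of every feature column against the target;
#' columns pass if their p-value beats `alpha / n_features` (Bonferroni)
#' *and* `|r| > r_min`. Constant columns have undefined correlation and
#' are excluded with a warning.
#'
#' @param X a [feature_table][assemble_features()] or numeric matrix.
#' @param target numeric target (e.g. age) of length `nrow(X)`.
#' @param rule a [selection_rule()].
#' @return list with `selected` (column indices), and `stats` (data
#'   frame of `r` and `p` per feature).
#' @export
select_features <- function(X, target, rule = selection_rule()) {
  n <- nrow(X)
  if (n < 3L) abort_validation("need at least 3 trials")
  if (length(target) != n) abort_validation("`target` length must match rows of X")
  m <- ncol(X)
  sds <- apply(X, 2L, stats::sd)
  const <- which(is.na(sds) | sds == 0)
  if (length(const))
    warning(sprintf("%d constant column(s) excluded from selection", length(const)),
            call. = FALSE)
  r <- suppressWarnings(as.numeric(stats::cor(X, target)))
  r[const] <- NA_real_
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-15))
  p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  thr <- rule$alpha / m
  selected <- which(!is.na(r) & p < thr & abs(r) > rule$r_min)
  list(selected = selected,
       stats = data.frame(feature = colnames(X) %||% paste0("f", seq_len(m)),
                          r = r, p = p))
}

#' Save / load a feature table as CSV with a JSON sidecar
#'
#' @param X a [feature_table][assemble_features()].
#' @param path CSV file path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return `feature_table_save` invisibly returns `path`;
#'   `feature_table_load` returns the table.
#' @export
feature_table_save <- function(X, path) {
  utils::write.csv(as.data.frame(unclass(X)), path, row.names = FALSE)
  side <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(list(names = colnames(X),
                            provenance = attr(X, "provenance")),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname feature_table_save
#' @export
feature_table_load <- function(path) {
  X <- as.matrix(utils::read.csv(path, check.names = FALSE))
  side <- sub("\\.csv$", ".json", path)
  prov <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else NULL
  structure(X, class = c("feature_table", class(X)),
            provenance = prov$provenance)
}
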