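# High-gamma feature extraction and related preprocessing.

# Analytic-signal magnitude via the frequency-domain construction: zero the
# negative frequencies, double the positive ones, inverse transform. x is a
# numeric vector.
analytic_envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

#' Extract normalized high-gamma features
#'
#' Turns raw electrode time series into the frames-by-electrodes feature
#' array the decoder consumes: a 4th-order zero-phase Butterworth band-pass
#' (70-150 Hz) isolates the high-gamma component, the analytic-signal
#' magnitude gives its amplitude envelope, an anti-aliased resampling brings
#' it to `frame_rate`, and each electrode is z-scored over the recording.
#' All-zero (artifact-excluded) channels stay all-zero.
#'
#' @param raw Numeric matrix, samples x electrodes.
#' @param fs Sampling rate of `raw` in Hz; must comfortably cover the band
#'   (`fs > 300`).
#' @param frame_rate Output frame rate in Hz (default 125).
#' @param band Pass band in Hz, default `c(70, 150)`.
#' @param normalize Apply the per-electrode z-score (default TRUE; FALSE
#'   exposes the raw band envelope, mainly for filter diagnostics).
#' @return Numeric matrix, frames x electrodes.
#' @export
extract_high_gamma <- function(raw, fs, frame_rate = 125, band = c(70, 150),
                               normalize = TRUE) {
  stopifnot(is.matrix(raw), all(is.finite(raw)))
  if (fs <= 2 * band[2]) {
    rlang::abort(paste0("fs = ", fs, " Hz is too low for the ", band[1], "-",
                        band[2], " Hz band"))
  }
  bp <- signal::butter(4, band / (fs / 2), type = "pass")
  lp <- signal::butter(4, min(0.45 * frame_rate, band[1] * 0.9) / (fs / 2),
                       type = "low")
  t_in <- (seq_len(nrow(raw)) - 1) / fs
  n_out <- floor(nrow(raw) / fs * frame_rate)
  t_out <- (seq_len(n_out) - 1) / frame_rate
  out <- matrix(0, n_out, ncol(raw))
  for (e in seq_len(ncol(raw))) {
    x <- raw[, e]
    if (all(x == 0)) next # excluded channel: keep the zero column
    env <- analytic_envelope(signal::filtfilt(bp, x))
    env <- signal::filtfilt(lp, env) # anti-alias before resampling
    out[, e] <- stats::approx(t_in, env, xout = t_out, rule = 2)$y
  }
  if (normalize) zscore_channels(out) else out
}

# per-electrode z-score with a guard for constant channels
zscore_channels <- function(x) {
  mu <- colMeans(x)
  sd_ <- apply(x, 2, stats::sd)
  keep <- sd_ > 0
  x[, keep] <- sweep(sweep(x[, keep, drop = FALSE], 2, mu[keep]), 2,
                     sd_[keep], "/")
  x[, !keep] <- 0
  x
}

#' Savitzky-Golay temporal smoothing
#'
#' Denoises the high-gamma features along the frame axis with a
#' Savitzky-Golay filter (3rd-order polynomial, window 11), the temporal
#' smoothing step applied after envelope extraction. Output has the same
#' length as the input; edge frames come from the filter's polynomial edge
#' treatment, and exactness guarantees apply to interior frames.
#'
#' @param x Numeric matrix, frames x electrodes (frames >= window).
#' @param order Polynomial order (default 3).
#' @param window Window length in frames (default 11, odd).
#' @return Smoothed matrix of the same shape.
#' @export
savgol_smooth <- function(x, order = 3, window = 11) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  if (nrow(x) < window) {
    rlang::abort(paste0("need at least ", window, " frames, got ", nrow(x)))
  }
  apply(x, 2, function(col) signal::sgolayfilt(col, p = order, n = window))
}

#' Select active electrodes by pooled standard deviation
#'
#' Pools each electrode's signal over all supplied trials and keeps the
#' electrodes whose standard deviation exceeds `threshold`. Optionally the
#' primary grid electrodes are always retained regardless of the threshold.
#'
#' @param trials List of frames-x-electrodes matrices (or a single matrix).
#' @param threshold Standard-deviation threshold (same units as the
#'   features).
#' @param always_keep Optional integer indices always retained (e.g. the
#'   8x8 grid electrodes).
#' @return Sorted integer vector of selected electrode indices.
#' @export
select_active_electrodes <- function(trials, threshold, always_keep = integer()) {
  if (is.matrix(trials)) trials <- list(trials)
  stopifnot(length(trials) >= 1)
  pooled <- do.call(rbind, trials)
  sds <- apply(pooled, 2, stats::sd)
  sort(unique(c(which(sds > threshold), as.integer(always_keep))))
}

#' Temporally shuffle a trial (chance-level control)
#'
#' Permutes the frames of a feature array with a seeded uniform random
#' permutation applied identically to all electrodes. Used as the control
#' condition: a decoder evaluated on temporally shuffled inputs should fall
#' to near-chance performance.
#'
#' @param trial_features Numeric matrix, frames x electrodes.
#' @param seed Integer seed; the same seed reproduces the same permutation.
#' @return The row-permuted matrix.
#' @export
shuffle_control <- function(trial_features, seed) {
  stopifnot(is.matrix(trial_features))
  perm <- with_seed(seed, sample.int(nrow(trial_features)))
  trial_features[perm, , drop = FALSE]
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
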