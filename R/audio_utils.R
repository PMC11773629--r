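# Audio demo utilities: phase-less spectrogram inversion and 16-bit PCM WAV
# output. These support listening to decoded speech; they are demo tools,
# not part of the evaluated decoding pipeline.

stft_mats <- function(n_fft) {
  k <- 0:(n_fft / 2)
  t(exp(-2i * pi * outer(k, 0:(n_fft - 1)) / n_fft))
}

#' Invert a magnitude spectrogram to a waveform (Griffin-Lim)
#'
#' Treats the T x F spectrogram as the magnitude of a short-time Fourier
#' transform with `n_fft = 2 (F - 1)` and hop `fs / frame_rate`, and runs
#' iterative phase reconstruction. Quality is demo-grade.
#'
#' @param spec T x F magnitude spectrogram.
#' @param frame_rate Spectrogram frame rate in Hz.
#' @param fs Output sampling rate in Hz (default 16000; `fs / frame_rate`
#'   must be a whole number of samples).
#' @param n_iter Griffin-Lim iterations (default 30).
#' @return Numeric waveform in \[-1, 1\].
#' @export
griffin_lim <- function(spec, frame_rate = 125, fs = 16000, n_iter = 30) {
  T <- nrow(spec)
  n_fft <- 2L * (ncol(spec) - 1L)
  hop <- fs / frame_rate
  stopifnot(hop == round(hop))
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(n_fft) / n_fft) # hann
  n_out <- (T - 1) * hop + n_fft
  kidx <- seq_len(ncol(spec))
  synth_frames <- function(Sc) {
    x <- numeric(n_out)
    wsum <- numeric(n_out)
    for (t in seq_len(T)) {
      full <- c(Sc[t, ], Conj(Sc[t, ncol(spec) - 1:(ncol(spec) - 2)]))
      fr <- Re(stats::fft(full, inverse = TRUE)) / n_fft
      at <- (t - 1) * hop
      x[at + seq_len(n_fft)] <- x[at + seq_len(n_fft)] + fr * win
      wsum[at + seq_len(n_fft)] <- wsum[at + seq_len(n_fft)] + win^2
    }
    x / pmax(wsum, 1e-8)
  }
  analyze <- function(x) {
    out <- matrix(0i, T, ncol(spec))
    for (t in seq_len(T)) {
      at <- (t - 1) * hop
      fr <- x[at + seq_len(n_fft)] * win
      out[t, ] <- stats::fft(fr)[kidx]
    }
    out
  }
  phase <- matrix(exp(2i * pi * 0.25), T, ncol(spec))
  for (i in seq_len(n_iter)) {
    x <- synth_frames(spec * phase)
    Z <- analyze(x)
    phase <- Z / pmax(Mod(Z), 1e-12)
  }
  x <- synth_frames(spec * phase)
  mx <- max(abs(x), 1e-9)
  x / mx
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param samples Numeric waveform in \[-1, 1\].
#' @param path Output path.
#' @param fs Sampling rate in Hz.
#' @return `path`, invisibly.
#' @export
wav_write <- function(samples, path, fs = 16000) {
  pcm <- as.integer(round(pmax(pmin(samples, 1), -1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_data <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + n_data, con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")  # PCM
  writeBin(1L, con, size = 2, endian = "little")  # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_data, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
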