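# Evaluation metrics: spectrogram correlation (PCC), STOI+ and mel-cepstral
# distortion, plus per-participant aggregation.

#' Mel filterbank matrix
#'
#' Triangular filters on the mel scale (`m = 2595 log10(1 + f/700)`) spanning
#' 0 to `fmax`, returned as an F x n_mels projection matrix for linear-bin
#' magnitude spectrograms.
#'
#' @param n_bins Number of linear bins.
#' @param fmax Upper frequency edge in Hz.
#' @param n_mels Number of mel bands (default 40).
#' @return `n_bins` x `n_mels` matrix.
#' @export
mel_filterbank <- function(n_bins, fmax = 8000, n_mels = 40) {
  hz2mel <- function(f) 2595 * log10(1 + f / 700)
  mel2hz <- function(m) 700 * (10^(m / 2595) - 1)
  freq <- spec_freq_axis(n_bins, fmax)
  pts <- mel2hz(seq(0, hz2mel(fmax), length.out = n_mels + 2))
  fb <- matrix(0, n_bins, n_mels)
  for (k in seq_len(n_mels)) {
    lo <- pts[k]; ce <- pts[k + 1]; hi <- pts[k + 2]
    up <- (freq - lo) / (ce - lo)
    down <- (hi - freq) / (hi - ce)
    fb[, k] <- pmax(0, pmin(up, down))
  }
  fb
}

# one-third-octave rectangular band matrix for linear bins; bands start at
# f_start and step by 2^(1/3); every band gets at least its nearest bin
third_octave_bands <- function(n_bins, fmax = 8000, n_bands = 15,
                               f_start = 150) {
  freq <- spec_freq_axis(n_bins, fmax)
  cf <- f_start * 2^((seq_len(n_bands) - 1) / 3)
  cf <- cf[cf < fmax]
  O <- matrix(0, n_bins, length(cf))
  for (k in seq_along(cf)) {
    inband <- freq >= cf[k] * 2^(-1 / 6) & freq < cf[k] * 2^(1 / 6)
    if (!any(inband)) inband[which.min(abs(freq - cf[k]))] <- TRUE
    O[inband, k] <- 1
  }
  O
}

#' Pearson correlation between decoded and reference spectrograms
#'
#' Correlation over all time-frequency bins of one trial, the primary
#' decoding accuracy metric.
#'
#' @param decoded,truth Same-shape numeric matrices.
#' @return Scalar in \[-1, 1\].
#' @export
pcc <- function(decoded, truth) {
  if (!identical(dim(decoded), dim(truth))) rlang::abort("shapes differ")
  if (stats::sd(decoded) == 0 || stats::sd(truth) == 0) {
    rlang::abort("PCC undefined: zero variance input")
  }
  stats::cor(as.vector(decoded), as.vector(truth))
}

#' STOI+ intelligibility metric
#'
#' Short-time objective intelligibility, the clipping-free variant whose
#' value lies in \[-1, 1\]: magnitude spectrograms are projected onto
#' one-third-octave bands (15 bands from 150 Hz), and the correlation between
#' the decoded and reference band envelopes, normalized per short segment
#' (default 30 frames), is averaged over bands and segments. Operates
#' directly on the package's spectrogram representation. Band/segment pairs
#' where either envelope is constant carry no intelligibility information and
#' are excluded from the average.
#'
#' @param decoded,reference Aligned T x F magnitude spectrograms.
#' @param seg_len Segment length in frames (default 30; shortened to T for
#'   short inputs).
#' @return Scalar in \[-1, 1\].
#' @export
stoi_plus <- function(decoded, reference, seg_len = 30) {
  if (!identical(dim(decoded), dim(reference))) rlang::abort("shapes differ")
  T <- nrow(decoded)
  if (T < 2) rlang::abort("input shorter than one analysis segment")
  O <- third_octave_bands(ncol(decoded))
  Ed <- sqrt(decoded^2 %*% O)
  Er <- sqrt(reference^2 %*% O)
  L <- min(seg_len, T)
  starts <- seq(1, T - L + 1, by = L)
  vals <- c()
  for (s in starts) {
    rows <- s:(s + L - 1)
    for (k in seq_len(ncol(O))) {
      x <- Ed[rows, k]; y <- Er[rows, k]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) next
      vals <- c(vals, stats::cor(x, y))
    }
  }
  if (!length(vals)) rlang::abort("all band envelopes constant; STOI+ undefined")
  mean(vals)
}

# DCT-II matrix (orthonormal), n x n_out
dct2_matrix <- function(n, n_out) {
  D <- matrix(0, n, n_out)
  for (k in seq_len(n_out)) {
    D[, k] <- cos(pi * (k - 1) * (seq_len(n) - 0.5) / n) *
      if (k == 1) sqrt(1 / n) else sqrt(2 / n)
  }
  D
}

#' Mel-cepstral coefficients of a spectrogram
#'
#' Mel filterbank -> log -> DCT-II, keeping `n_coef` coefficients per frame
#' (c0 first).
#'
#' @param spec T x F magnitude spectrogram.
#' @param n_coef Number of cepstral coefficients (default 25).
#' @param n_mels Mel bands used internally (default 40).
#' @param fmax Upper frequency edge (default 8000).
#' @return T x `n_coef` coefficient matrix.
#' @export
mel_cepstra <- function(spec, n_coef = 25, n_mels = 40, fmax = 8000) {
  fb <- mel_filterbank(ncol(spec), fmax, n_mels)
  E <- log(spec %*% fb + 1e-5)
  E %*% dct2_matrix(n_mels, n_coef)
}

#' Mel-cepstral distortion
#'
#' Per frame, `MCD = (10 / ln 10) * sqrt(sum_{0 < d < 25} (mc_d - mc_d_hat)^2)`
#' over mel-cepstral coefficients, averaged over frames. The summation runs
#' over d = 1..24, excluding the energy coefficient c0: the representation
#' carries 25 coefficients per frame but 24 enter the distance. Inputs may be
#' spectrograms (converted via [mel_cepstra()]) or precomputed T x 25
#' coefficient matrices.
#'
#' @param decoded,reference Aligned spectrograms or cepstra.
#' @param input `"spectrogram"` (default) or `"cepstra"`.
#' @return Mean per-frame distortion (dB-like, >= 0).
#' @export
mcd <- function(decoded, reference, input = c("spectrogram", "cepstra")) {
  input <- match.arg(input)
  if (nrow(decoded) != nrow(reference)) rlang::abort("frame counts differ")
  if (input == "spectrogram") {
    decoded <- mel_cepstra(decoded)
    reference <- mel_cepstra(reference)
  }
  if (ncol(decoded) != ncol(reference)) rlang::abort("coefficient counts differ")
  d <- (decoded - reference)[, 2:25, drop = FALSE]
  mean((10 / log(10)) * sqrt(rowSums(d^2)))
}

#' Evaluate decoded trials for one participant
#'
#' Computes PCC, STOI+ and MCD per test trial and their participant-level
#' means, the aggregation used for cohort-level comparison figures.
#'
#' @param decoded,truth Lists of aligned spectrograms (same length/order).
#' @param participant_id Label for the output row.
#' @return A one-row tibble (`participant_id`, `pcc`, `stoi_plus`, `mcd`,
#'   `n_trials`) with the per-trial table in `attr(, "trials")`.
#' @export
evaluate_participant <- function(decoded, truth, participant_id = "p") {
  stopifnot(length(decoded) == length(truth), length(decoded) >= 1)
  trials <- purrr::map2_dfr(decoded, truth, function(d, s) {
    tibble::tibble(pcc = pcc(d, s), stoi_plus = stoi_plus(d, s),
                   mcd = mcd(d, s))
  })
  trials <- dplyr::mutate(trials,
                          participant_id = participant_id,
                          trial = dplyr::row_number(), .before = 1)
  out <- tibble::tibble(participant_id = participant_id,
                        pcc = mean(trials$pcc),
                        stoi_plus = mean(trials$stoi_plus),
                        mcd = mean(trials$mcd),
                        n_trials = nrow(trials))
  attr(out, "trials") <- trials
  class(out) <- c("twspeech_eval", class(out))
  out
}

#' Paired or unpaired comparison of per-participant metrics
#'
#' Thin reporting wrapper around the Wilcoxon signed-rank (paired) or
#' rank-sum (unpaired) test, two-sided, as used for model comparisons.
#'
#' @param a,b Numeric vectors of per-participant metric means.
#' @param paired Logical (default TRUE: signed-rank).
#' @return Tidy one-row tibble with the statistic and p value.
#' @export
compare_metrics <- function(a, b, paired = TRUE) {
  ht <- stats::wilcox.test(a, b, paired = paired, exact = FALSE)
  tibble::tibble(method = ht$method, statistic = unname(ht$statistic),
                 p_value = ht$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Box plot of per-trial evaluation metrics
#'
#' @param object A tibble from [evaluate_participant()] (uses the per-trial
#'   table stored in its attributes), or a bound row set of several.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.twspeech_eval <- function(object, ...) {
  trials <- attr(object, "trials")
  long <- tidyr::pivot_longer(trials, c("pcc", "stoi_plus", "mcd"),
                              names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$participant_id,
                                     y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL)
}
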