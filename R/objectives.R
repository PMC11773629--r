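# Training losses for neural-to-speech decoding. Each loss exists as a
# tape-node version (used inside training) and a numeric wrapper with the
# documented error contract; the wrapper runs the same code on constants.

#' Loss weights for neural-decoder training
#'
#' Defaults follow the composite objective
#' `L = L_MSS + 1.2 L_STOI + 0.1 L_supervision + 1.0 L_reference`,
#' with per-parameter reference weights all 1.
#'
#' @param lambda_stoi Weight of the intelligibility loss (default 1.2).
#' @param lambda_sup Weight of the pitch/formant supervision loss (default 0.1).
#' @param lambda_ref Weight of the parameter reference loss (default 1.0).
#' @param per_param 18-vector of per-parameter weights inside the reference
#'   loss (default all 1).
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(lambda_stoi = 1.2, lambda_sup = 0.1,
                         lambda_ref = 1.0, per_param = rep(1, 18)) {
  stopifnot(lambda_stoi >= 0, lambda_sup >= 0, lambda_ref >= 0,
            length(per_param) == 18, all(per_param >= 0))
  structure(list(lambda_stoi = lambda_stoi, lambda_sup = lambda_sup,
                 lambda_ref = lambda_ref, per_param = as.numeric(per_param)),
            class = "loss_weights")
}

reference_node <- function(pred, ref, per_param = rep(1, 18)) {
  d <- ag_square(ag_sub(pred, ref))
  ag_sum(ag_mul(d, matrix(per_param, 1)))
}

#' Reference loss between predicted and encoder speech parameters
#'
#' `sum_{i,t} lambda_i (pred[t,i] - ref[t,i])^2` over the 18 parameters:
#' the decoder is trained to match the parameters the speech encoder
#' extracts from the ground-truth spectrogram.
#'
#' @param pred,ref T x 18 parameter matrices.
#' @param w A [loss_weights()] object (uses `per_param`).
#' @return Scalar loss.
#' @export
reference_loss <- function(pred, ref, w = loss_weights()) {
  if (!identical(dim(pred), dim(ref))) {
    rlang::abort("pred and ref must have identical T x 18 shape")
  }
  ag_value(reference_node(ag_const(pred), ag_const(ref), w$per_param))[1]
}

mss_node <- function(pred, truth, mel, eps = 1e-5) {
  lin_a <- ag_mean(ag_abs(ag_sub(pred, truth)))
  lin_l <- ag_mean(ag_abs(ag_sub(ag_log(pred, eps), ag_log(truth, eps))))
  pm <- ag_matmul(pred, mel)
  tm <- ag_matmul(truth, mel)
  mel_a <- ag_mean(ag_abs(ag_sub(pm, tm)))
  mel_l <- ag_mean(ag_abs(ag_sub(ag_log(pm, eps), ag_log(tm, eps))))
  ag_add(ag_add(lin_a, lin_l), ag_add(mel_a, mel_l))
}

#' Multi-scale spectral loss
#'
#' Mean absolute difference of magnitudes plus mean absolute difference of
#' log-magnitudes, computed on the linear spectrogram and on its
#' mel-filterbank projection, summed. This is the spectrogram-matching term
#' of the composite objective.
#'
#' @param pred_spec,true_spec T x F non-negative magnitude spectrograms.
#' @param fmax Upper frequency edge (for the mel projection), default 8000.
#' @return Scalar loss (>= 0, 0 iff identical).
#' @export
mss_loss <- function(pred_spec, true_spec, fmax = 8000) {
  if (!identical(dim(pred_spec), dim(true_spec))) {
    rlang::abort("spectrogram shapes differ")
  }
  if (any(pred_spec < 0) || any(true_spec < 0)) {
    rlang::abort("magnitude spectrograms must be non-negative")
  }
  mel <- mel_filterbank(ncol(pred_spec), fmax)
  ag_value(mss_node(ag_const(pred_spec), ag_const(true_spec), mel))[1]
}

stoi_node <- function(pred, truth_val, octave_mat, seg_len = 30, eps = 1e-8) {
  T <- nrow(truth_val)
  L <- min(seg_len, T)
  Ep <- ag_sqrt(ag_matmul(ag_square(pred), octave_mat), eps = 1e-12)
  Er <- sqrt((truth_val^2) %*% octave_mat + 1e-12)
  starts <- seq(1, T - L + 1, by = L)
  corrs <- vector("list", length(starts))
  for (si in seq_along(starts)) {
    rows <- starts[si]:(starts[si] + L - 1)
    Xs <- ag_gather_rows(Ep, as.integer(rows))
    Xc <- ag_sub(Xs, ag_colmeans(Xs))
    Y <- Er[rows, , drop = FALSE]
    Yc <- Y - matrix(colMeans(Y), L, ncol(Y), byrow = TRUE)
    num <- ag_colsums(ag_mul(Xc, Yc))
    den <- ag_mul(ag_sqrt(ag_colsums(ag_square(Xc)), eps = eps),
                  matrix(sqrt(colSums(Yc^2) + eps), 1))
    corrs[[si]] <- ag_div(num, ag_add(den, eps))
  }
  ag_mean(ag_cbind(corrs))
}

#' Intelligibility loss (negative STOI+)
#'
#' `-STOI+` computed on the spectrogram path (see [stoi_plus()]): band
#' envelopes from one-third-octave projections, correlations of normalized
#' envelopes over short segments, averaged, negated. This version is the
#' differentiable surrogate used during training (small epsilons regularize
#' the normalizations); the evaluation metric in [stoi_plus()] is exact.
#'
#' @param pred_spec,true_spec T x F magnitude spectrograms (aligned).
#' @param seg_len Segment length in frames (default 30).
#' @return Scalar in \[-1, 1\].
#' @export
stoi_loss <- function(pred_spec, true_spec, seg_len = 30) {
  if (!identical(dim(pred_spec), dim(true_spec))) {
    rlang::abort("spectrogram shapes differ")
  }
  if (nrow(pred_spec) < 2) rlang::abort("input shorter than one analysis segment")
  O <- third_octave_bands(ncol(pred_spec))
  -ag_value(stoi_node(ag_const(pred_spec), true_spec, O, seg_len = seg_len))[1]
}

supervision_node <- function(pred, ref_freqs) {
  mask <- matrix(as.numeric(is.finite(ref_freqs)), nrow(ref_freqs))
  ref0 <- ifelse(is.finite(ref_freqs), ref_freqs, 0)
  d <- ag_mul(ag_sub(ag_slice_cols(pred, 1:5), ref0), mask)
  ag_sum(ag_square(d))
}

#' Pitch/formant supervision loss
#'
#' Squared distance between the predicted `f0, f1..f4` tracks and externally
#' supplied reference frequencies (in the clinical pipeline these come from a
#' Praat-style tracker; in the synthetic pipeline the generator's true
#' trajectories are used). `NaN` marks frames without supervision (e.g.
#' unvoiced), which contribute zero.
#'
#' @param pred T x 18 parameter matrix.
#' @param ref_freqs T x 5 matrix of reference `f0, f1..f4` in Hz, `NaN` for
#'   unsupervised frames.
#' @return Scalar loss in Hz^2.
#' @export
supervision_loss <- function(pred, ref_freqs) {
  stopifnot(ncol(pred) == 18, ncol(ref_freqs) == 5,
            nrow(pred) == nrow(ref_freqs))
  ag_value(supervision_node(ag_const(pred), ref_freqs))[1]
}

#' Combine loss components into the training objective
#'
#' `L = L_MSS + lambda_stoi * L_STOI + lambda_sup * L_supervision +
#' lambda_ref * L_reference` with default weights (1, 1.2, 0.1, 1.0).
#'
#' @param components Named list/vector with `mss`, `stoi`, `supervision`,
#'   `reference`.
#' @param w A [loss_weights()].
#' @return Scalar total loss.
#' @export
total_loss <- function(components, w = loss_weights()) {
  components <- as.list(components)
  need <- c("mss", "stoi", "supervision", "reference")
  stopifnot(all(need %in% names(components)))
  for (nm in need) {
    if (is.na(components[[nm]])) {
      rlang::abort(paste0("loss component '", nm, "' is not finite"))
    }
  }
  components$mss + w$lambda_stoi * components$stoi +
    w$lambda_sup * components$supervision + w$lambda_ref * components$reference
}
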