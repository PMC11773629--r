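# The 18-parameter speech representation, the differentiable source-filter
# synthesizer, and the speech encoder trained by spectrogram auto-encoding.

#' Names of the 18 per-frame speech parameters, in storage order
#'
#' The fixed column order of every parameter array in the package:
#' pitch `f0`; formant center frequencies `f1`-`f6` (Hz) with amplitudes
#' `a1`-`a6`; unvoiced filter center `fu`, bandwidth `bu` and amplitude `au`;
#' voicing mix `alpha` in \[0, 1\]; loudness `L`.
#' @return Character vector of length 18.
#' @export
speech_param_names <- function() {
  c("f0", paste0("f", 1:6), paste0("a", 1:6), "fu", "bu", "au", "alpha", "L")
}

#' Physiological ranges of the speech parameters
#'
#' Lower/upper bounds used three ways: the synthetic trajectory generator
#' samples inside them, the bounded output heads of the encoder and the
#' neural decoder map onto them, and [validate_speech_params()] checks them.
#' Frequency bands are staggered (f1 200-1000 Hz, f2 500-2500 Hz, ...) as in
#' natural speech, which also makes the formant slots identifiable during
#' auto-encoder training.
#'
#' @return An 18 x 2 matrix with rownames from [speech_param_names()] and
#'   columns `lo`, `hi`.
#' @export
speech_param_ranges <- function() {
  r <- rbind(
    f0 = c(80, 300),
    f1 = c(200, 1000), f2 = c(500, 2500), f3 = c(1500, 3500),
    f4 = c(2500, 4500), f5 = c(3500, 6000), f6 = c(4500, 7500),
    a1 = c(0, 1), a2 = c(0, 1), a3 = c(0, 1),
    a4 = c(0, 1), a5 = c(0, 1), a6 = c(0, 1),
    fu = c(1000, 6000), bu = c(200, 2000), au = c(0, 1),
    alpha = c(0, 1), L = c(0, 1)
  )
  colnames(r) <- c("lo", "hi")
  r
}

#' Validate a speech-parameter array
#'
#' Checks the invariants of the representation: shape T x 18, finite values,
#' `alpha` in \[0, 1\], amplitudes and loudness non-negative, and all
#' frequencies inside (0, `fmax`).
#'
#' @param params Numeric matrix T x 18 in [speech_param_names()] order.
#' @param fmax Nyquist-like upper frequency bound in Hz (default 8000).
#' @return `params`, invisibly; errors describe the violated invariant.
#' @export
validate_speech_params <- function(params, fmax = 8000) {
  if (!is.matrix(params) || ncol(params) != 18) {
    rlang::abort("speech parameters must be a T x 18 matrix")
  }
  if (!all(is.finite(params))) rlang::abort("non-finite speech parameter")
  nm <- speech_param_names()
  freq_cols <- c(1:7, 14)
  fr <- params[, freq_cols, drop = FALSE]
  if (any(fr <= 0) || any(fr >= fmax)) {
    rlang::abort(paste0("frequencies must lie in (0, ", fmax, ") Hz"))
  }
  amp_cols <- match(c(paste0("a", 1:6), "au", "L"), nm)
  if (any(params[, amp_cols] < 0)) rlang::abort("amplitudes and L must be >= 0")
  al <- params[, match("alpha", nm)]
  if (any(al < 0 | al > 1)) rlang::abort("alpha must lie in [0, 1]")
  bu <- params[, match("bu", nm)]
  if (any(bu <= 0)) rlang::abort("bu must be positive")
  invisible(params)
}

#' Linear frequency axis of the spectrogram representation
#' @param n_bins Number of linear-frequency bins (default 128).
#' @param fmax Upper edge in Hz (default 8000).
#' @return Bin-center frequencies in Hz.
#' @export
spec_freq_axis <- function(n_bins = 128, fmax = 8000) {
  (seq_len(n_bins) - 0.5) * fmax / n_bins
}

#' Default per-formant bandwidths (Hz) of the synthesizer
#' @return Numeric vector of length 6.
#' @export
formant_bandwidths <- function() c(80, 120, 160, 200, 240, 280)

# Differentiable synthesizer on tape nodes. P: node (T x 18). Returns node
# (T x F). Every parameter flows through differentiable ops only.
synth_node <- function(P, n_bins = 128, fmax = 8000,
                       bandwidths = formant_bandwidths(),
                       harmonics = FALSE, harmonic_depth = 0.8) {
  freq <- spec_freq_axis(n_bins, fmax)
  lnf <- matrix(log(freq), 1)
  col <- function(i) ag_slice_cols(P, i)
  voiced <- NULL
  for (i in 1:6) {
    fc <- col(i + 1)
    a <- col(i + 7)
    # unit-peak Gaussian bump in log-frequency, sigma = b / (2 fc)
    s <- ag_div(ag_scale(fc, 2), bandwidths[i])   # 2 fc / b = 1/sigma
    z <- ag_mul(ag_sub(lnf, ag_log(fc)), s)
    G <- ag_exp(ag_scale(ag_square(z), -0.5))
    term <- ag_mul(G, a)
    voiced <- if (is.null(voiced)) term else ag_add(voiced, term)
  }
  if (harmonics) {
    ratio <- ag_exp(ag_sub(lnf, ag_log(col(1)))) # f / f0
    comb <- ag_add(ag_scale(ag_add(ag_cos(ag_scale(ratio, 2 * pi)), 1),
                            harmonic_depth / 2),
                   1 - harmonic_depth)
    voiced <- ag_mul(voiced, comb)
  }
  fu <- col(14); bu <- col(15); au <- col(16)
  su <- ag_div(ag_scale(fu, 2), bu)
  zu <- ag_mul(ag_sub(lnf, ag_log(fu)), su)
  Gu <- ag_exp(ag_scale(ag_square(zu), -0.5))
  alpha <- col(17); L <- col(18)
  mix <- ag_add(ag_mul(alpha, voiced),
                ag_mul(ag_mul(ag_sub(1, alpha), au), Gu))
  ag_mul(L, mix)
}

#' Synthesize a spectrogram from speech-parameter trajectories
#'
#' The differentiable source-filter stand-in synthesizer: per frame t,
#' \deqn{S(t,f) = L_t [ \alpha_t \sum_{i=1}^{6} a_{i,t} G(f; f_{i,t}, b_i) H(f; f_{0,t})
#'   + (1-\alpha_t) a_{u,t} G(f; f_{u,t}, b_{u,t}) ]}
#' where `G` is a unit-peak Gaussian bump in log-frequency (bandwidth `b`
#' interpreted as the bump's full width at the center, sigma = b/(2 fc) in
#' log-frequency) and `H` an optional soft harmonic comb at multiples of f0
#' (off by default). The function is differentiable in every parameter; the
#' same code path runs under the package's tape for training.
#'
#' @param params T x 18 matrix in [speech_param_names()] order.
#' @param n_bins Number of linear-frequency bins (default 128).
#' @param fmax Upper frequency edge in Hz (default 8000); all frequency
#'   parameters must be below it.
#' @param bandwidths Fixed per-formant bandwidths in Hz.
#' @param harmonics Logical; modulate the voiced part by a soft harmonic
#'   comb at multiples of f0.
#' @return Numeric magnitude spectrogram, T x `n_bins` (non-negative).
#' @export
#' @examples
#' p <- matrix(rep(c(120, 500, 1500, 2500, 3500, 4500, 5500,
#'                   1, .5, .25, .1, .05, .02, 3000, 800, .3, .9, .8),
#'             each = 4), 4, 18)
#' S <- synthesize(p)
#' dim(S)
synthesize <- function(params, n_bins = 128, fmax = 8000,
                       bandwidths = formant_bandwidths(), harmonics = FALSE) {
  validate_speech_params(params, fmax = fmax)
  ag_value(synth_node(ag_const(params), n_bins = n_bins, fmax = fmax,
                      bandwidths = bandwidths, harmonics = harmonics))
}

# ---- bounded output map ------------------------------------------------------

# raw (n x 18) node -> bounded speech parameters via per-column sigmoid
# scaling onto speech_param_ranges(). Frequencies are kept strictly inside
# their band, amplitudes/alpha/L inside [lo, hi].
bounded_param_node <- function(raw) {
  r <- speech_param_ranges()
  lo <- matrix(r[, "lo"], 1)
  span <- matrix(r[, "hi"] - r[, "lo"], 1)
  ag_add(ag_mul(ag_sigmoid(raw), span), lo)
}

# ---- temporal convolution helpers -------------------------------------------

# index vectors for +/-1 frame shifts of B stacked sequences of length T
# (row r = (b-1)*T + t); out-of-trial neighbours map to 0 (zero row)
shift_indices <- function(B, T) {
  r <- seq_len(B * T)
  t <- (r - 1L) %% T + 1L
  m1 <- ifelse(t == 1L, 0L, r - 1L)
  p1 <- ifelse(t == T, 0L, r + 1L)
  list(m1 = as.integer(m1), p1 = as.integer(p1))
}

# temporal conv, kernel 3, stride 1, zero padding at trial edges
conv3_node <- function(x, w_prev, w_cur, w_next, b, idx) {
  y <- ag_linear(x, w_cur, b)
  y <- ag_add(y, ag_matmul(ag_gather_rows(x, idx$m1), w_prev))
  ag_add(y, ag_matmul(ag_gather_rows(x, idx$p1), w_next))
}

# ---- speech encoder ----------------------------------------------------------

# truncated normal, fan-in scaled by default so that signal magnitude is
# preserved through stacks without normalization layers
tn_init <- function(nr, nc, sd = sqrt(2 / nr)) {
  v <- stats::rnorm(nr * nc, 0, sd)
  v <- pmin(pmax(v, -2 * sd), 2 * sd)
  matrix(v, nr, nc)
}

#' Initialize a speech encoder
#'
#' The encoder maps a spectrogram to per-frame speech parameters with two
#' temporal convolution layers (kernel 3) followed by a two-layer per-frame
#' MLP whose outputs are bounded onto [speech_param_ranges()] by sigmoid
#' scaling.
#'
#' @param n_bins Spectrogram bins (default 128).
#' @param hidden Latent width (default 64).
#' @param seed Integer seed for weight initialization.
#' @return A `speech_encoder` object (list of parameter nodes + sizes).
#' @export
speech_encoder_init <- function(n_bins = 128, hidden = 64, seed = 1) {
  p <- with_seed(seed, list(
    c1_prev = tn_init(n_bins, hidden), c1_cur = tn_init(n_bins, hidden),
    c1_next = tn_init(n_bins, hidden), c1_b = matrix(0, 1, hidden),
    c2_prev = tn_init(hidden, hidden), c2_cur = tn_init(hidden, hidden),
    c2_next = tn_init(hidden, hidden), c2_b = matrix(0, 1, hidden),
    m1_w = tn_init(hidden, hidden), m1_b = matrix(0, 1, hidden),
    m2_w = tn_init(hidden, 18), m2_b = matrix(0, 1, 18)
  ))
  params <- lapply(p, ag_param)
  structure(list(params = params, n_bins = n_bins, hidden = hidden),
            class = "speech_encoder")
}

encoder_params <- function(enc) enc$params

# forward on a node: spec rows stacked as B trials x T frames
encoder_forward <- function(enc, spec, B, T) {
  idx <- shift_indices(B, T)
  p <- enc$params
  h <- ag_leakyrelu(conv3_node(spec, p$c1_prev, p$c1_cur, p$c1_next, p$c1_b, idx))
  h <- ag_leakyrelu(conv3_node(h, p$c2_prev, p$c2_cur, p$c2_next, p$c2_b, idx))
  h <- ag_leakyrelu(ag_linear(h, p$m1_w, p$m1_b))
  bounded_param_node(ag_linear(h, p$m2_w, p$m2_b))
}

#' Encode a spectrogram into speech parameters
#'
#' Applies a (typically trained) speech encoder to one spectrogram. Output
#' ranges are enforced by the bounded output map, so the result always
#' satisfies [validate_speech_params()].
#'
#' @param spec Numeric T x n_bins magnitude spectrogram.
#' @param encoder A `speech_encoder`, e.g. from [train_speech_autoencoder()].
#' @return T x 18 speech-parameter matrix.
#' @export
speech_encode <- function(spec, encoder) {
  stopifnot(inherits(encoder, "speech_encoder"),
            is.matrix(spec), ncol(spec) == encoder$n_bins)
  out <- ag_value(encoder_forward(encoder, ag_const(spec), 1L, nrow(spec)))
  colnames(out) <- speech_param_names()
  out
}

#' Train the speech auto-encoder (speech-to-speech step)
#'
#' First step of the two-step pipeline: the encoder extracts 18 speech
#' parameters per frame and the differentiable synthesizer reconstructs the
#' spectrogram; both ends are matched with the multi-scale spectral loss.
#' Only the encoder has trainable weights (the synthesizer is a fixed
#' parametric map), so this fits the encoder to invert the synthesizer on
#' the participant's speech.
#'
#' @param specs List of T x n_bins spectrograms (equal T).
#' @param epochs Training epochs (default 60).
#' @param lr Adam learning rate (default 1e-3).
#' @param batch Trials per step (default 8).
#' @param seed Seed for initialization and batch order.
#' @param n_bins,fmax,bandwidths,harmonics Synthesizer settings; must match
#'   the spectrograms.
#' @param hidden Encoder latent width.
#' @param verbose Print the loss once per 10 epochs.
#' @return A `speech_model`: list with `encoder`, the synthesizer settings,
#'   and the per-epoch `loss` trace.
#' @export
train_speech_autoencoder <- function(specs, epochs = 60, lr = 1e-3, batch = 8,
                                     seed = 1, n_bins = 128, fmax = 8000,
                                     bandwidths = formant_bandwidths(),
                                     harmonics = FALSE, hidden = 64,
                                     verbose = FALSE) {
  stopifnot(length(specs) >= 1)
  T <- nrow(specs[[1]])
  enc <- speech_encoder_init(n_bins = n_bins, hidden = hidden, seed = seed)
  opt <- adam_init(enc$params, lr = lr)
  mel <- mel_filterbank(n_bins, fmax)
  n <- length(specs)
  losses <- numeric(epochs)
  order_seed <- seed + 1e6
  for (ep in seq_len(epochs)) {
    ord <- with_seed(order_seed + ep, sample.int(n))
    tot <- 0
    for (start in seq(1, n, by = batch)) {
      ids <- ord[start:min(start + batch - 1, n)]
      S <- do.call(rbind, specs[ids])
      ag_zero_grads(enc$params)
      ag_tape_start()
      P <- encoder_forward(enc, ag_const(S), length(ids), T)
      R <- synth_node(P, n_bins = n_bins, fmax = fmax,
                      bandwidths = bandwidths, harmonics = harmonics)
      loss <- mss_node(R, ag_const(S), mel)
      lv <- ag_value(loss)[1]
      if (!is.finite(lv)) {
        ag_tape_stop()
        rlang::abort(paste0("non-finite auto-encoder loss at epoch ", ep))
      }
      ag_backward(loss)
      ag_tape_stop()
      opt <- adam_step(opt, clip = 1)
      tot <- tot + lv * length(ids)
    }
    losses[ep] <- tot / n
    if (verbose && ep %% 10 == 0) {
      message(sprintf("autoencoder epoch %d loss %.5f", ep, losses[ep]))
    }
  }
  structure(list(encoder = enc, n_bins = n_bins, fmax = fmax,
                 bandwidths = bandwidths, harmonics = harmonics,
                 loss = losses),
            class = "speech_model")
}

#' @export
print.speech_model <- function(x, ...) {
  cat("<speech_model> encoder hidden ", x$encoder$hidden, ", ", x$n_bins,
      " bins, final auto-encoding loss ",
      formatC(utils::tail(x$loss, 1), digits = 4, format = "f"), "\n", sep = "")
  invisible(x)
}

#' Reconstruct a spectrogram through the auto-encoder
#' @param spec T x n_bins spectrogram.
#' @param model A `speech_model`.
#' @return Reconstructed T x n_bins spectrogram.
#' @export
speech_reconstruct <- function(spec, model) {
  synthesize(speech_encode(spec, model$encoder), n_bins = model$n_bins,
             fmax = model$fmax, bandwidths = model$bandwidths,
             harmonics = model$harmonics)
}
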