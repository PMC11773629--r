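# Shared oracles and fixtures, all built in code.

# A plain valid speech-parameter matrix used across files.
base_params <- function(T = 6) {
  p <- matrix(rep(c(120, 500, 1500, 2500, 3500, 4500, 5500,
                    0.9, 0.5, 0.25, 0.1, 0.05, 0.02,
                    3000, 800, 0.3, 0.8, 0.6), each = T), T, 18)
  colnames(p) <- twspeech::speech_param_names()
  p
}

# Finite-difference gradient of scalar-valued fn(x) (x a matrix) at x.
fd_grad <- function(fn, x, h = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  g
}

# Analytic gradient of a scalar loss w.r.t. one ag_param input, by running
# forward() (which must take the param node and return a scalar node) under a
# fresh tape.
ag_grad_of <- function(forward, p) {
  twspeech:::ag_tape_start()
  on.exit(twspeech:::ag_tape_stop())
  loss <- forward(p)
  twspeech:::ag_backward(loss)
  p$grad
}

rel_err <- function(a, b) {
  max(abs(a - b)) / max(1e-8, max(abs(a)), max(abs(b)))
}

# Dense masked multi-head scaled-cosine attention oracle. Tokens x (n x C),
# mask (n x n logical: TRUE = may attend), bias array [n, n, head].
dense_cosine_attention <- function(x, wqkv, bqkv, wproj, bproj, tau, bias_arr,
                                   mask, n_head, eps = 1e-6) {
  C <- ncol(x)
  d <- C / n_head
  qkv <- x %*% wqkv + matrix(bqkv, nrow(x), 3 * C, byrow = TRUE)
  O <- matrix(0, nrow(x), C)
  for (h in seq_len(n_head)) {
    qc <- ((h - 1) * d + 1):(h * d)
    q <- qkv[, qc, drop = FALSE]
    k <- qkv[, C + qc, drop = FALSE]
    v <- qkv[, 2 * C + qc, drop = FALSE]
    qh <- q / sqrt(rowSums(q^2) + eps)
    kh <- k / sqrt(rowSums(k^2) + eps)
    S <- tcrossprod(qh, kh) / tau[h] + bias_arr[, , h]
    S[!mask] <- -Inf
    A <- exp(S - apply(S, 1, max))
    A <- A / rowSums(A)
    O[, qc] <- A %*% v
  }
  O %*% wproj + matrix(bproj, nrow(x), C, byrow = TRUE)
}
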