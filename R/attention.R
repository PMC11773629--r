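# Fused windowed multi-head scaled-cosine attention.
#
# Tokens arrive window-major: rows are grouped as B x nw blocks of M tokens
# (B trials, nw temporal windows per trial, M = Wt x Ns tokens per window).
# Within each window, per head h:
#   SIM(q_i, k_j) = cos(q_i, k_j) / tau_h + B_ij
#   out = softmax_rows(SIM) %*% V
# Heads are concatenated and linearly projected. The positional bias B is
# shared across trials in the batch (it depends only on electrode anatomy and
# temporal slot, not on the signal), laid out as ((w-1)*Nh + h-1)*M + i rows.
#
# Implemented as one tape node with a hand-derived backward pass; correctness
# is checked in the tests against a dense masked-attention oracle and finite
# differences.

ag_window_attention <- function(x, wqkv, bqkv, wproj, bproj, tau, bias,
                                B, nw, M, n_head, eps = 1e-6) {
  xv <- ag_value(x)
  C <- ncol(xv)
  stopifnot(C %% n_head == 0L, nrow(xv) == B * nw * M)
  d <- C %/% n_head
  wqkv_v <- ag_value(wqkv); bqkv_v <- ag_value(bqkv)
  wproj_v <- ag_value(wproj); bproj_v <- ag_value(bproj)
  tau_v <- as.numeric(ag_value(tau))
  bias_v <- ag_value(bias)
  stopifnot(length(tau_v) == n_head,
            nrow(bias_v) == nw * n_head * M, ncol(bias_v) == M)

  qkv <- xv %*% wqkv_v
  qkv <- qkv + matrix(bqkv_v, nrow(qkv), ncol(qkv), byrow = TRUE)

  nblk <- B * nw
  O <- matrix(0, nrow(xv), C)
  st <- vector("list", nblk) # cached per-block forward state
  for (blk in seq_len(nblk)) {
    w <- (blk - 1L) %% nw + 1L
    rows <- ((blk - 1L) * M + 1L):(blk * M)
    hstate <- vector("list", n_head)
    for (h in seq_len(n_head)) {
      qc <- ((h - 1L) * d + 1L):(h * d)
      q <- qkv[rows, qc, drop = FALSE]
      k <- qkv[rows, C + qc, drop = FALSE]
      v <- qkv[rows, 2L * C + qc, drop = FALSE]
      qn_ <- sqrt(rowSums(q * q) + eps)
      kn_ <- sqrt(rowSums(k * k) + eps)
      qh <- q / qn_
      kh <- k / kn_
      Cm <- tcrossprod(qh, kh)
      brow <- ((w - 1L) * n_head + h - 1L) * M
      S <- Cm / tau_v[h] + bias_v[(brow + 1L):(brow + M), , drop = FALSE]
      A <- exp(S - max(S))
      A <- A / rowSums(A)
      O[rows, qc] <- A %*% v
      hstate[[h]] <- list(qh = qh, kh = kh, qn = qn_, kn = kn_, v = v,
                          A = A, Cm = Cm)
    }
    st[[blk]] <- hstate
  }
  out <- O %*% wproj_v
  out <- out + matrix(bproj_v, nrow(out), ncol(out), byrow = TRUE)

  inputs <- list(x, wqkv, bqkv, wproj, bproj, tau, bias)
  if (!any(vapply(inputs, ag_req, logical(1)))) return(ag_op(out, inputs, list()))

  # shared backward: compute once, then hand out per-input pieces
  cache <- new.env(parent = emptyenv())
  backall <- function(g) {
    if (!is.null(cache$done)) return(invisible(NULL))
    dO <- g %*% t(wproj_v)
    dwproj <- crossprod(O, g)
    dbproj <- matrix(colSums(g), 1L)
    dQKV <- matrix(0, nrow(xv), 3L * C)
    dbias <- matrix(0, nrow(bias_v), M)
    dtau <- numeric(n_head)
    for (blk in seq_len(nblk)) {
      w <- (blk - 1L) %% nw + 1L
      rows <- ((blk - 1L) * M + 1L):(blk * M)
      for (h in seq_len(n_head)) {
        s <- st[[blk]][[h]]
        qc <- ((h - 1L) * d + 1L):(h * d)
        dOh <- dO[rows, qc, drop = FALSE]
        dA <- tcrossprod(dOh, s$v)
        dv <- crossprod(s$A, dOh)
        tmp <- dA * s$A
        dS <- tmp - s$A * rowSums(tmp)
        brow <- ((w - 1L) * n_head + h - 1L) * M
        dbias[(brow + 1L):(brow + M), ] <-
          dbias[(brow + 1L):(brow + M), ] + dS
        dtau[h] <- dtau[h] - sum(dS * s$Cm) / tau_v[h]^2
        dqh <- (dS %*% s$kh) / tau_v[h]
        dkh <- crossprod(dS, s$qh) / tau_v[h]
        dq <- (dqh - s$qh * rowSums(dqh * s$qh)) / s$qn
        dk <- (dkh - s$kh * rowSums(dkh * s$kh)) / s$kn
        dQKV[rows, qc] <- dq
        dQKV[rows, C + qc] <- dk
        dQKV[rows, 2L * C + qc] <- dv
      }
    }
    cache$dx <- dQKV %*% t(wqkv_v)
    cache$dwqkv <- crossprod(xv, dQKV)
    cache$dbqkv <- matrix(colSums(dQKV), 1L)
    cache$dwproj <- dwproj
    cache$dbproj <- dbproj
    cache$dtau <- matrix(dtau, 1L)
    cache$dbias <- dbias
    cache$done <- TRUE
    invisible(NULL)
  }
  ag_op(out, inputs, list(
    function(g, nd) { backall(g); cache$dx },
    function(g, nd) { backall(g); cache$dwqkv },
    function(g, nd) { backall(g); cache$dbqkv },
    function(g, nd) { backall(g); cache$dwproj },
    function(g, nd) { backall(g); cache$dbproj },
    function(g, nd) { backall(g); cache$dtau },
    function(g, nd) { backall(g); cache$dbias }
  ))
}
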