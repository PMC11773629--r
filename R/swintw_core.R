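# Grid-free temporal-window transformer decoder.
#
# Tokens are formed per electrode from temporal patches; attention is
# windowed in time only and spans all electrodes, with a positional bias
# built from MNI coordinates (2-layer MLP on the 12-vector of both tokens'
# coordinates, time indices and their differences) plus a dot product of
# learnable region embeddings. Three stages (2, 2, 6 layers) with temporal
# patch merging between them, then an MLP to C', spatial max pooling over
# electrodes, transposed-convolution upsampling back to T frames, and a
# convolutional prediction head emitting the 18 speech parameters per frame.

#' Decoder configuration
#'
#' Defaults are the reference architecture: patch size `W = 4`, temporal
#' window `Wt = 4`, base latent `C = 96` mapped down to `C_out = 32` after
#' stage 3, stage depths (2, 2, 6) with (3, 6, 12) attention heads. The
#' transposed-convolution upsampler has `log2(4 W)` stride-2 layers so the
#' output frame count equals the input `T`; the validator therefore requires
#' `4 * W` to be a power of two. Smaller values of `C` (divisible by the head
#' counts) give proportionally cheaper decoders for scaled-down experiments.
#'
#' @param W Temporal patch size.
#' @param Wt Temporal window size (attention is computed among `Wt x N`
#'   tokens per window; the partition is cyclically shifted by `Wt/2` every
#'   other layer).
#' @param C Base latent dimension.
#' @param C_out Latent dimension after the post-stage MLP.
#' @param stage_depths,stage_heads Per-stage layer and head counts.
#' @param mlp_ratio Hidden width multiplier of each transformer block MLP.
#' @param bias_hidden Hidden width of the 2-layer positional-bias MLP.
#' @param C_r Region-embedding dimension.
#' @param tau_init Initial attention temperature (learnable, kept positive
#'   and >= 0.01 via a softplus parameterization).
#' @param head_hidden Hidden widths of the post-stage-3 MLP; derived from `C`
#'   when `NULL` (the reference 384 -> 196 -> 96 -> 32 at `C = 96`).
#' @return A `decoder_config` list.
#' @export
decoder_config <- function(W = 4, Wt = 4, C = 96, C_out = 32,
                           stage_depths = c(2, 2, 6),
                           stage_heads = c(3, 6, 12),
                           mlp_ratio = 4, bias_hidden = 32, C_r = 16,
                           tau_init = 0.1, head_hidden = NULL) {
  stopifnot(length(stage_depths) == 3, length(stage_heads) == 3)
  n_up <- log2(4 * W)
  if (n_up != round(n_up)) {
    rlang::abort("4*W must be a power of two so that upsampling restores T")
  }
  for (s in 1:3) {
    Cs <- C * 2^(s - 1)
    if (Cs %% stage_heads[s] != 0) {
      rlang::abort(paste0("stage ", s, " latent ", Cs,
                          " not divisible by ", stage_heads[s], " heads"))
    }
  }
  if (is.null(head_hidden)) head_hidden <- c(round(49 * C / 24), C)
  structure(list(W = W, Wt = Wt, C = C, C_out = C_out,
                 stage_depths = stage_depths, stage_heads = stage_heads,
                 mlp_ratio = mlp_ratio, bias_hidden = bias_hidden, C_r = C_r,
                 tau_init = tau_init, head_hidden = head_hidden,
                 n_up = as.integer(n_up)),
            class = "decoder_config")
}

#' Initialize a decoder
#'
#' Weight initialization is truncated normal (sd 0.02) for linear and
#' attention weights; the final layer of every positional-bias MLP starts at
#' zero so training begins bias-free.
#'
#' @param config A [decoder_config()].
#' @param n_regions Total region indices of the atlas (Unknown included);
#'   sizes the per-stage region-embedding dictionaries (left and right
#'   hemispheres occupy disjoint index ranges, so their embeddings are
#'   hemisphere-specific by construction).
#' @param seed Integer seed.
#' @return A `tw_decoder` model object.
#' @export
decoder_init <- function(config = decoder_config(), n_regions, seed = 1) {
  cf <- config
  p <- list()
  with_seed(seed, {
    p[["embed.w"]] <- tn_init(cf$W, cf$C)
    p[["embed.b"]] <- matrix(0, 1, cf$C)
    for (s in 1:3) {
      Cs <- cf$C * 2^(s - 1)
      Hs <- cf$stage_heads[s]
      rho0 <- log(exp(cf$tau_init - 0.01) - 1)
      for (l in seq_len(cf$stage_depths[s])) {
        id <- paste0("s", s, ".l", l, ".")
        p[[paste0(id, "attn.wqkv")]] <- tn_init(Cs, 3 * Cs)
        p[[paste0(id, "attn.bqkv")]] <- matrix(0, 1, 3 * Cs)
        p[[paste0(id, "attn.wproj")]] <- tn_init(Cs, Cs)
        p[[paste0(id, "attn.bproj")]] <- matrix(0, 1, Cs)
        p[[paste0(id, "attn.rho")]] <- matrix(rho0, 1, Hs)
        p[[paste0(id, "ln1.g")]] <- matrix(1, 1, Cs)
        p[[paste0(id, "ln1.b")]] <- matrix(0, 1, Cs)
        p[[paste0(id, "ln2.g")]] <- matrix(1, 1, Cs)
        p[[paste0(id, "ln2.b")]] <- matrix(0, 1, Cs)
        hm <- cf$mlp_ratio * Cs
        p[[paste0(id, "mlp.w1")]] <- tn_init(Cs, hm)
        p[[paste0(id, "mlp.b1")]] <- matrix(0, 1, hm)
        p[[paste0(id, "mlp.w2")]] <- tn_init(hm, Cs)
        p[[paste0(id, "mlp.b2")]] <- matrix(0, 1, Cs)
        p[[paste0(id, "bias.w1")]] <- tn_init(12, cf$bias_hidden)
        p[[paste0(id, "bias.b1")]] <- matrix(0, 1, cf$bias_hidden)
        p[[paste0(id, "bias.w2")]] <- matrix(0, cf$bias_hidden, Hs)
        p[[paste0(id, "bias.b2")]] <- matrix(0, 1, Hs)
      }
      p[[paste0("s", s, ".region")]] <- tn_init(n_regions, cf$C_r * Hs)
      if (s < 3) {
        p[[paste0("merge", s, ".w")]] <- tn_init(2 * Cs, 2 * Cs)
        p[[paste0("merge", s, ".b")]] <- matrix(0, 1, 2 * Cs)
      }
    }
    dims <- c(4 * cf$C, cf$head_hidden, cf$C_out)
    for (i in seq_len(length(dims) - 1)) {
      p[[paste0("post.w", i)]] <- tn_init(dims[i], dims[i + 1])
      p[[paste0("post.b", i)]] <- matrix(0, 1, dims[i + 1])
      if (i < length(dims) - 1) {
        p[[paste0("post.ln", i, ".g")]] <- matrix(1, 1, dims[i + 1])
        p[[paste0("post.ln", i, ".b")]] <- matrix(0, 1, dims[i + 1])
      }
    }
    for (k in seq_len(cf$n_up)) {
      for (j in 1:3) p[[paste0("up", k, ".w", j)]] <- tn_init(cf$C_out, cf$C_out)
      p[[paste0("up", k, ".b")]] <- matrix(0, 1, cf$C_out)
    }
    for (j in 1:2) {
      id <- paste0("head.c", j, ".")
      p[[paste0(id, "wp")]] <- tn_init(cf$C_out, cf$C_out)
      p[[paste0(id, "wc")]] <- tn_init(cf$C_out, cf$C_out)
      p[[paste0(id, "wn")]] <- tn_init(cf$C_out, cf$C_out)
      p[[paste0(id, "b")]] <- matrix(0, 1, cf$C_out)
    }
    p[["head.m1.w"]] <- tn_init(cf$C_out, cf$C_out)
    p[["head.m1.b"]] <- matrix(0, 1, cf$C_out)
    p[["head.m2.w"]] <- tn_init(cf$C_out, 18)
    p[["head.m2.b"]] <- matrix(0, 1, 18)
  })
  structure(list(params = lapply(p, ag_param), config = cf,
                 n_regions = as.integer(n_regions)),
            class = "tw_decoder")
}

#' @export
print.tw_decoder <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) length(p$value), numeric(1)))
  cat("<tw_decoder> C=", x$config$C, ", C_out=", x$config$C_out, ", stages (",
      paste(x$config$stage_depths, collapse = ","), ") x heads (",
      paste(x$config$stage_heads, collapse = ","), "), ",
      format(np, big.mark = ","), " parameters, ",
      x$n_regions, " region indices\n", sep = "")
  invisible(x)
}

#' Names of all decoder parameters (state-dictionary audit)
#'
#' Useful to verify that a shared multi-subject decoder carries no
#' participant-indexed parameters.
#' @param model A `tw_decoder`.
#' @return Character vector of parameter names.
#' @export
decoder_param_names <- function(model) names(model$params)

# ---- geometry plans ----------------------------------------------------------

# stage-wise temporal token counts for input length T
stage_schedule <- function(config, T) {
  Nt1 <- T / config$W
  c(Nt1, Nt1 / 2, Nt1 / 4)
}

validate_geometry <- function(config, T, N) {
  if (T %% config$W != 0) {
    rlang::abort(paste0("T = ", T, " not divisible by patch size W = ", config$W))
  }
  nts <- stage_schedule(config, T)
  for (s in 1:3) {
    if (nts[s] %% config$Wt != 0) {
      rlang::abort(paste0("stage ", s, ": N_t = ", nts[s],
                          " not divisible by window Wt = ", config$Wt))
    }
  }
  if (N < 1) rlang::abort("need at least one electrode")
  invisible(nts)
}

# window partition of temporal slots; returns actual temporal index per
# (window, slot). Shifted partitions cyclically roll by Wt/2.
window_slots <- function(Nt, Wt, shifted) {
  Nt <- as.integer(Nt); Wt <- as.integer(Wt)
  sh <- if (shifted) Wt %/% 2L else 0L
  pos <- seq_len(Nt)
  t_act <- ((pos - 1L - sh) %% Nt) + 1L
  matrix(t_act, nrow = Wt) # column w = slots of window w
}

# gather index (field -> window-major) and its inverse for B trials
window_index <- function(B, Nt, Ns, Wt, shifted) {
  B <- as.integer(B); Nt <- as.integer(Nt); Ns <- as.integer(Ns)
  Wt <- as.integer(Wt)
  slots <- window_slots(Nt, Wt, shifted)
  nw <- ncol(slots)
  # token order in window: slot-major, electrode fastest
  per_trial <- as.vector(vapply(seq_len(nw), function(w) {
    as.vector(vapply(slots[, w], function(t) {
      ((t - 1L) * Ns) + seq_len(Ns)
    }, integer(Ns)))
  }, integer(Wt * Ns)))
  idx <- as.vector(vapply(seq_len(B), function(b) {
    per_trial + (b - 1L) * Nt * Ns
  }, integer(Nt * Ns)))
  inv <- integer(length(idx))
  inv[idx] <- seq_along(idx)
  list(idx = as.integer(idx), inv = inv, nw = nw)
}

# pairwise bias-MLP input features for every window of a stage:
# (x_i, y_i, z_i, t_i, x_j, y_j, z_j, t_j, and the four differences),
# MNI in units of 100 mm, temporal index scaled to (0, 1)
pair_features <- function(mni, Nt, Wt, shifted) {
  Ns <- nrow(mni)
  slots <- window_slots(Nt, Wt, shifted)
  nw <- ncol(slots)
  M <- Wt * Ns
  coords <- mni / 100
  blocks <- vector("list", nw)
  for (w in seq_len(nw)) {
    tv <- (slots[, w] - 0.5) / Nt
    cw <- cbind(coords[rep(seq_len(Ns), times = Wt), , drop = FALSE],
                rep(tv, each = Ns))
    ci <- cw[rep(seq_len(M), each = M), , drop = FALSE]
    cj <- cw[rep(seq_len(M), times = M), , drop = FALSE]
    blocks[[w]] <- cbind(ci, cj, ci - cj)
  }
  do.call(rbind, blocks)
}

# full geometry plan for (layout sorted canonically, T frames, B trials)
decoder_plan <- function(config, layout, T, B) {
  Ns <- n_electrodes(layout)
  nts <- validate_geometry(config, T, Ns)
  mni <- layout_mni(layout)
  roi <- layout$electrodes$roi_index
  stages <- vector("list", 3)
  for (s in 1:3) {
    Nt <- nts[s]
    stages[[s]] <- list(
      Nt = Nt, M = config$Wt * Ns,
      roi_tok = rep(as.integer(roi), config$Wt),
      win = list(
        unshifted = c(window_index(B, Nt, Ns, config$Wt, FALSE),
                      list(F = pair_features(mni, Nt, config$Wt, FALSE))),
        shifted = c(window_index(B, Nt, Ns, config$Wt, TRUE),
                    list(F = pair_features(mni, Nt, config$Wt, TRUE)))
      )
    )
  }
  merges <- lapply(1:2, function(s) {
    Nt <- nts[s]; Nt2 <- Nt / 2
    grid <- expand.grid(e = seq_len(Ns), t2 = seq_len(Nt2), b = seq_len(B))
    base <- (grid$b - 1L) * Nt * Ns
    list(a = as.integer(base + (2L * grid$t2 - 2L) * Ns + grid$e),
         b = as.integer(base + (2L * grid$t2 - 1L) * Ns + grid$e))
  })
  # transposed-conv index maps: layer k upsamples length L -> 2L
  L <- nts[3]
  up_idx <- vector("list", config$n_up)
  for (k in seq_len(config$n_up)) {
    taps <- lapply(0:2, function(k0) {
      idx <- integer(B * 2 * L)
      for (b in seq_len(B)) {
        for (o0 in 0:(2 * L - 1)) {
          num <- o0 + 1 - k0
          l0 <- num / 2
          v <- 0L
          if (num %% 2 == 0 && l0 >= 0 && l0 < L) v <- (b - 1L) * L + l0 + 1L
          idx[(b - 1L) * 2L * L + o0 + 1L] <- v
        }
      }
      idx
    })
    up_idx[[k]] <- taps
    L <- 2L * L
  }
  list(Ns = Ns, T = T, B = B, nts = nts, stages = stages, merges = merges,
       up_idx = up_idx, head_idx = shift_indices(B, T))
}

# ---- forward pass ------------------------------------------------------------

# positional bias node for one layer: MLP on pair features + region-embedding
# dot products; returns the ((w-1)*Nh + h - 1)*M + i row layout consumed by
# ag_window_attention
bias_node <- function(p, id, region, stage, win, Hs, C_r) {
  M <- stage$M
  nw <- win$nw
  H1 <- ag_leakyrelu(ag_linear(ag_const(win$F),
                               p[[paste0(id, "bias.w1")]],
                               p[[paste0(id, "bias.b1")]]))
  BM <- ag_linear(H1, p[[paste0(id, "bias.w2")]], p[[paste0(id, "bias.b2")]])
  per_head_mlp <- lapply(seq_len(Hs), function(h) {
    ag_reshape_rowmajor(ag_slice_cols(BM, h), nw * M, M)
  })
  per_head_reg <- lapply(seq_len(Hs), function(h) {
    cols <- ((h - 1) * C_r + 1):(h * C_r)
    r_tok <- ag_gather_rows(ag_slice_cols(region, cols), stage$roi_tok + 1L)
    ag_matmul_t(r_tok, r_tok)
  })
  blocks <- vector("list", nw * Hs)
  for (w in seq_len(nw)) {
    rows_w <- as.integer(((w - 1) * M + 1):(w * M))
    for (h in seq_len(Hs)) {
      blocks[[(w - 1) * Hs + h]] <-
        ag_add(ag_gather_rows(per_head_mlp[[h]], rows_w), per_head_reg[[h]])
    }
  }
  ag_rbind(blocks)
}

transformer_layer <- function(X, p, id, region, stage, cf, B, shifted) {
  Hs <- ncol(ag_value(p[[paste0(id, "attn.rho")]]))
  win <- if (shifted) stage$win$shifted else stage$win$unshifted
  bias <- bias_node(p, id, region, stage, win, Hs, cf$C_r)
  tau <- ag_add(ag_softplus(p[[paste0(id, "attn.rho")]]), 0.01)
  Xw <- ag_gather_rows(X, win$idx)
  A <- ag_window_attention(Xw,
                           p[[paste0(id, "attn.wqkv")]], p[[paste0(id, "attn.bqkv")]],
                           p[[paste0(id, "attn.wproj")]], p[[paste0(id, "attn.bproj")]],
                           tau, bias, B = B, nw = win$nw, M = stage$M, n_head = Hs)
  A <- ag_gather_rows(A, win$inv)
  # residual post-norm block convention
  X <- ag_add(X, ag_layernorm(A, p[[paste0(id, "ln1.g")]], p[[paste0(id, "ln1.b")]]))
  H <- ag_leakyrelu(ag_linear(X, p[[paste0(id, "mlp.w1")]], p[[paste0(id, "mlp.b1")]]))
  H <- ag_linear(H, p[[paste0(id, "mlp.w2")]], p[[paste0(id, "mlp.b2")]])
  ag_add(X, ag_layernorm(H, p[[paste0(id, "ln2.g")]], p[[paste0(id, "ln2.b")]]))
}

# patches: stack B signals (T x Ns each, canonical electrode order) into the
# ((b-1)*Nt + t - 1)*Ns + e row layout of W-frame patches
build_patches <- function(signals, W) {
  B <- length(signals)
  T <- nrow(signals[[1]]); Ns <- ncol(signals[[1]])
  Nt <- T %/% W
  P <- matrix(0, B * Nt * Ns, W)
  for (b in seq_len(B)) {
    rows <- ((b - 1) * Nt * Ns + 1):(b * Nt * Ns)
    for (j in seq_len(W)) {
      P[rows, j] <- as.vector(t(signals[[b]][seq(j, T, by = W), , drop = FALSE]))
    }
  }
  P
}

# full decoder forward on a plan; returns node (B*T x 18) of bounded params
decoder_forward_node <- function(model, plan, patches) {
  p <- model$params
  cf <- model$config
  B <- plan$B
  X <- ag_linear(ag_const(patches), p[["embed.w"]], p[["embed.b"]])
  for (s in 1:3) {
    stage <- plan$stages[[s]]
    region <- p[[paste0("s", s, ".region")]]
    for (l in seq_len(cf$stage_depths[s])) {
      id <- paste0("s", s, ".l", l, ".")
      X <- transformer_layer(X, p, id, region, stage, cf, B, shifted = l %% 2 == 0)
    }
    if (s < 3) {
      mg <- plan$merges[[s]]
      Xm <- ag_cbind(list(ag_gather_rows(X, mg$a), ag_gather_rows(X, mg$b)))
      X <- ag_linear(Xm, p[[paste0("merge", s, ".w")]], p[[paste0("merge", s, ".b")]])
    }
  }
  n_post <- length(cf$head_hidden) + 1
  for (i in seq_len(n_post)) {
    X <- ag_linear(X, p[[paste0("post.w", i)]], p[[paste0("post.b", i)]])
    if (i < n_post) {
      X <- ag_leakyrelu(ag_layernorm(X, p[[paste0("post.ln", i, ".g")]],
                                     p[[paste0("post.ln", i, ".b")]]))
    }
  }
  X <- ag_block_rowmax(X, plan$Ns) # spatial max pool over electrodes
  for (k in seq_len(cf$n_up)) {
    taps <- plan$up_idx[[k]]
    Y <- ag_linear(ag_gather_rows(X, taps[[1]]), p[[paste0("up", k, ".w1")]],
                   p[[paste0("up", k, ".b")]])
    Y <- ag_add(Y, ag_matmul(ag_gather_rows(X, taps[[2]]), p[[paste0("up", k, ".w2")]]))
    Y <- ag_add(Y, ag_matmul(ag_gather_rows(X, taps[[3]]), p[[paste0("up", k, ".w3")]]))
    X <- ag_leakyrelu(Y)
  }
  for (j in 1:2) {
    id <- paste0("head.c", j, ".")
    X <- ag_leakyrelu(conv3_node(X, p[[paste0(id, "wp")]], p[[paste0(id, "wc")]],
                                 p[[paste0(id, "wn")]], p[[paste0(id, "b")]],
                                 plan$head_idx))
  }
  X <- ag_leakyrelu(ag_linear(X, p[["head.m1.w"]], p[["head.m1.b"]]))
  bounded_param_node(ag_linear(X, p[["head.m2.w"]], p[["head.m2.b"]]))
}

#' Decode speech parameters from one neural trial
#'
#' Runs the full decoder pipeline on a frames-by-electrodes feature array.
#' Electrodes are internally reordered into a canonical order derived from
#' their ids, which makes the output exactly invariant to the order in which
#' electrodes (features and layout jointly) are supplied; no grid structure
#' is assumed, and any electrode count >= 1 works.
#'
#' @param signal T x N numeric matrix (columns in layout order).
#' @param layout The matching `electrode_layout`.
#' @param model A `tw_decoder` (e.g. from [train_subject()]).
#' @return T x 18 speech-parameter matrix (columns named).
#' @export
decode_forward <- function(signal, layout, model) {
  stopifnot(is.matrix(signal), inherits(model, "tw_decoder"))
  if (ncol(signal) != n_electrodes(layout)) {
    rlang::abort(paste0("signal has ", ncol(signal), " electrodes but layout has ",
                        n_electrodes(layout)))
  }
  ord <- layout_canonical_order(layout)
  lay <- permute_layout(layout, ord)
  plan <- decoder_plan(model$config, lay, nrow(signal), 1L)
  patches <- build_patches(list(signal[, ord, drop = FALSE]), model$config$W)
  out <- ag_value(decoder_forward_node(model, plan, patches))
  colnames(out) <- speech_param_names()
  out
}

# ---- checkpointing -----------------------------------------------------------

#' Save / load a decoder checkpoint
#'
#' The checkpoint stores parameter values, the configuration and the region
#' count in a single RDS file.
#'
#' @param model A `tw_decoder`.
#' @param path Checkpoint path.
#' @return `path` invisibly (`save_decoder`); the restored `tw_decoder`
#'   (`load_decoder`).
#' @export
save_decoder <- function(model, path) {
  saveRDS(list(values = lapply(model$params, function(p) p$value),
               config = unclass(model$config),
               n_regions = model$n_regions), path)
  invisible(path)
}

#' @rdname save_decoder
#' @export
load_decoder <- function(path) {
  ck <- readRDS(path)
  cf <- structure(ck$config, class = "decoder_config")
  structure(list(params = lapply(ck$values, ag_param), config = cf,
                 n_regions = ck$n_regions),
            class = "tw_decoder")
}
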