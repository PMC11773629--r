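tiny_cfg <- function() {
  decoder_config(W = 2, Wt = 2, C = 12, C_out = 6, stage_heads = c(2, 2, 4),
                 mlp_ratio = 2, C_r = 3, bias_hidden = 6)
}

atlas <- load_atlas()

test_that("temporal patching yields (T/W) x N tokens and rejects bad T", {
  expect_equal(nrow(twspeech:::build_patches(list(matrix(0, 64, 16)), 4)),
               (64 / 4) * 16)
  expect_equal(nrow(twspeech:::build_patches(list(matrix(0, 4, 1)), 4)), 1)
  expect_error(twspeech:::validate_geometry(decoder_config(), 6, 1),
               "not divisible")
})

test_that("patch contents map electrode-wise frame blocks", {
  X <- matrix(seq_len(8 * 2), 8, 2) # frames x electrodes
  P <- twspeech:::build_patches(list(X), 4)
  # row ordering: (t', e) with e fastest
  expect_equal(P[1, ], X[1:4, 1])
  expect_equal(P[2, ], X[1:4, 2])
  expect_equal(P[3, ], X[5:8, 1])
})

test_that("window partition counts, shifted slots, and the full-attention limit", {
  wi <- twspeech:::window_index(1, 16, 64, 4, FALSE)
  expect_equal(wi$nw, 4)
  expect_equal(length(wi$idx), 16 * 64)
  # each window holds Wt * Ns = 256 tokens
  expect_equal(length(wi$idx) / wi$nw, 256)
  # shifted windows: temporal indices {7,8,1,2}, {3,4,5,6} for Nt=8, Wt=4
  slots <- twspeech:::window_slots(8, 4, TRUE)
  expect_equal(slots[, 1], c(7L, 8L, 1L, 2L))
  expect_equal(slots[, 2], c(3L, 4L, 5L, 6L))
  # Wt = Nt: a single window spans everything (full attention)
  expect_equal(twspeech:::window_index(1, 4, 3, 4, FALSE)$nw, 1)
})

test_that("positional bias matches a hand-computed MLP + region dot product", {
  cf <- tiny_cfg()
  m <- decoder_init(cf, n_regions = atlas$n_regions, seed = 2)
  lay <- gen_layout("seeg_only", "left", seed = 3, n_electrodes = 2)
  lay <- permute_layout(lay, twspeech:::layout_canonical_order(lay))
  plan <- twspeech:::decoder_plan(cf, lay, 16, 1)
  stage <- plan$stages[[1]]
  # put recognizable weights into the layer-1 bias MLP
  set.seed(4)
  m$params[["s1.l1.bias.w1"]]$value <- matrix(rnorm(12 * cf$bias_hidden, 0, 0.3),
                                              12, cf$bias_hidden)
  m$params[["s1.l1.bias.b1"]]$value <- matrix(rnorm(cf$bias_hidden, 0, 0.1), 1)
  m$params[["s1.l1.bias.w2"]]$value <- matrix(rnorm(cf$bias_hidden * 2, 0, 0.3),
                                              cf$bias_hidden, 2)
  m$params[["s1.l1.bias.b2"]]$value <- matrix(c(0.05, -0.02), 1)
  bias <- twspeech:::ag_value(twspeech:::bias_node(
    m$params, "s1.l1.", m$params[["s1.region"]], stage, stage$win$unshifted,
    Hs = 2, C_r = cf$C_r))
  M <- stage$M; nw <- stage$win$unshifted$nw
  expect_equal(dim(bias), c(nw * 2 * M, M))
  # independent matrix-arithmetic oracle for a few (w, h, i, j) entries
  lrelu <- function(x) ifelse(x > 0, x, 0.01 * x)
  Fmat <- stage$win$unshifted$F
  RE <- m$params[["s1.region"]]$value
  roi <- stage$roi_tok + 1L
  for (case in list(c(1, 1, 1, 1), c(2, 2, 3, 4), c(4, 1, 4, 2))) {
    w <- case[1]; h <- case[2]; i <- case[3]; j <- case[4]
    f <- Fmat[(w - 1) * M * M + (i - 1) * M + j, , drop = FALSE]
    h1 <- lrelu(f %*% m$params[["s1.l1.bias.w1"]]$value +
                  as.vector(m$params[["s1.l1.bias.b1"]]$value))
    mlp <- (h1 %*% m$params[["s1.l1.bias.w2"]]$value)[1, h] +
      m$params[["s1.l1.bias.b2"]]$value[1, h]
    rcols <- ((h - 1) * cf$C_r + 1):(h * cf$C_r)
    reg <- sum(RE[roi[i], rcols] * RE[roi[j], rcols])
    expect_equal(bias[((w - 1) * 2 + h - 1) * M + i, j], mlp + reg,
                 tolerance = 1e-10)
  }
  # i = j: MLP input has zero differences; region part is ||r_i||^2
  f_ii <- Fmat[(0) * M * M + (1 - 1) * M + 1, ]
  expect_equal(unname(f_ii[9:12]), rep(0, 4))
  # region term is symmetric
  for (h in 1:2) {
    rows_h <- ((h - 1) * M + 1):(h * M) # window 1 block for head h
    rcols <- ((h - 1) * cf$C_r + 1):(h * cf$C_r)
    RB <- RE[roi, rcols] %*% t(RE[roi, rcols])
    expect_equal(RB, t(RB))
  }
})

test_that("single-token windows reduce attention to the value projection", {
  C <- 4
  x <- matrix(rnorm(C), 1, C)
  wqkv <- matrix(rnorm(3 * C * C, 0, 0.4), C, 3 * C)
  wproj <- diag(C)
  out <- twspeech:::ag_value(twspeech:::ag_window_attention(
    twspeech:::ag_const(x), wqkv, matrix(0, 1, 3 * C), wproj, matrix(0, 1, C),
    matrix(c(0.5), 1), matrix(0, 1, 1), B = 1, nw = 1, M = 1, n_head = 1))
  v <- (x %*% wqkv)[, (2 * C + 1):(3 * C), drop = FALSE]
  expect_equal(out, v, tolerance = 1e-12)
})

test_that("attention rows are a proper softmax (rows sum to one)", {
  set.seed(11)
  M <- 6; C <- 4
  x <- matrix(rnorm(M * C), M, C)
  qkv <- cbind(diag(C)[rep(1:4, length.out = C), ], diag(C), diag(C))
  wqkv <- matrix(rnorm(C * 3 * C, 0, 0.3), C, 3 * C)
  # reconstruct A from the oracle formula with zero bias and check rows
  qkvv <- x %*% wqkv
  q <- qkvv[, 1:C]; k <- qkvv[, C + 1:C]
  qh <- q / sqrt(rowSums(q^2) + 1e-6); kh <- k / sqrt(rowSums(k^2) + 1e-6)
  A <- exp(tcrossprod(qh, kh) / 0.3)
  A <- A / rowSums(A)
  expect_equal(rowSums(A), rep(1, M), tolerance = 1e-12)
})

test_that("token/latent schedule follows the closed form and merges halve tokens", {
  expect_equal(twspeech:::stage_schedule(decoder_config(), 64), c(16, 8, 4))
  cf <- tiny_cfg()
  m <- decoder_init(cf, n_regions = atlas$n_regions, seed = 1)
  lay <- gen_layout("seeg_only", "left", seed = 5, n_electrodes = 3)
  plan <- twspeech:::decoder_plan(cf, lay, 32, 2) # Nt schedule 16, 8, 4
  expect_equal(length(plan$merges[[1]]$a), 2 * 8 * 3)  # B * Nt/2 * Ns
  expect_equal(length(plan$merges[[2]]$a), 2 * 4 * 3)
  # merged pairs are temporally consecutive tokens of the same electrode
  expect_equal(plan$merges[[1]]$b - plan$merges[[1]]$a, rep(3L, 2 * 8 * 3))
})

test_that("decode_forward produces T x 18 bounded parameters for any layout", {
  cf <- tiny_cfg()
  m <- decoder_init(cf, n_regions = atlas$n_regions, seed = 1)
  for (N in c(5, 16)) {
    lay <- gen_layout("seeg_only", "left", seed = N, n_electrodes = N)
    X <- matrix(rnorm(32 * N), 32, N)
    out <- decode_forward(X, lay, m)
    expect_equal(dim(out), c(32, 18))
    expect_error(validate_speech_params(out), NA)
  }
})

test_that("decoding is exactly invariant to joint electrode permutation", {
  cf <- tiny_cfg()
  m <- decoder_init(cf, n_regions = atlas$n_regions, seed = 6)
  lay <- gen_layout("grid_plus_extras", "right", seed = 8)
  N <- twspeech:::n_electrodes(lay)
  X <- matrix(rnorm(32 * N), 32, N)
  ref <- decode_forward(X, lay, m)
  for (s in 1:3) {
    perm <- twspeech:::with_seed(s, sample(N))
    out <- decode_forward(X[, perm], permute_layout(lay, perm), m)
    expect_identical(out, ref)
  }
})

test_that("upsampling restores T for admissible W and rejects inconsistent W", {
  expect_error(decoder_config(W = 3), "power of two")
  cf2 <- decoder_config(W = 2, Wt = 2, C = 8, C_out = 4,
                        stage_heads = c(2, 2, 2), mlp_ratio = 1, C_r = 2,
                        bias_hidden = 4)
  expect_equal(cf2$n_up, 3L) # 4W = 8 = 2^3
  m <- decoder_init(cf2, n_regions = atlas$n_regions, seed = 2)
  lay <- gen_layout("seeg_only", "left", seed = 2, n_electrodes = 2)
  out <- decode_forward(matrix(rnorm(16 * 2), 16, 2), lay, m)
  expect_equal(nrow(out), 16)
})

test_that("checkpoints round-trip the decoder exactly", {
  cf <- tiny_cfg()
  m <- decoder_init(cf, n_regions = atlas$n_regions, seed = 4)
  lay <- gen_layout("seeg_only", "left", seed = 4, n_electrodes = 4)
  X <- matrix(rnorm(32 * 4), 32, 4)
  f <- tempfile(fileext = ".rds")
  save_decoder(m, f)
  m2 <- load_decoder(f)
  expect_identical(decode_forward(X, lay, m2), decode_forward(X, lay, m))
  expect_identical(decoder_param_names(m2), decoder_param_names(m))
})

test_that("a full stage of stacked shifted windows equals dense masked attention", {
  # one stage, two layers (unshifted then shifted), <= 32 tokens
  cf <- decoder_config(W = 2, C = 8, C_out = 4, stage_depths = c(2, 2, 6),
                       stage_heads = c(2, 2, 2), mlp_ratio = 1, C_r = 2,
                       bias_hidden = 4)
  m <- decoder_init(cf, n_regions = atlas$n_regions, seed = 9)
  lay <- gen_layout("seeg_only", "left", seed = 9, n_electrodes = 2)
  lay <- permute_layout(lay, twspeech:::layout_canonical_order(lay))
  T <- 32 # Nt1 = 8 temporal tokens x 2 electrodes = 16 tokens
  plan <- twspeech:::decoder_plan(cf, lay, T, 1)
  stage <- plan$stages[[1]]
  Nt <- stage$Nt; Ns <- 2L; n <- Nt * Ns
  set.seed(10)
  X0 <- matrix(rnorm(n * cf$C, 0, 0.5), n, cf$C)
  p <- m$params
  # package path: two stacked layers (second shifted)
  Xn <- twspeech:::ag_const(X0)
  for (l in 1:2) {
    Xn <- twspeech:::transformer_layer(Xn, p, paste0("s1.l", l, "."),
                                       p[["s1.region"]], stage, cf, 1,
                                       shifted = l %% 2 == 0)
  }
  got <- twspeech:::ag_value(Xn)

  # oracle path: dense attention with block-diagonal (rolled) masks
  lrelu <- function(x) ifelse(x > 0, x, 0.01 * x)
  layernorm <- function(x, g, b) {
    mu <- rowMeans(x); v <- rowMeans((x - mu)^2)
    ((x - mu) / sqrt(v + 1e-5)) * matrix(g, nrow(x), length(g), byrow = TRUE) +
      matrix(b, nrow(x), length(b), byrow = TRUE)
  }
  Xo <- X0
  for (l in 1:2) {
    id <- paste0("s1.l", l, ".")
    shifted <- l %% 2 == 0
    win <- if (shifted) stage$win$shifted else stage$win$unshifted
    slots <- twspeech:::window_slots(Nt, cf$Wt, shifted)
    mask <- matrix(FALSE, n, n)
    M <- stage$M
    bias_arr <- array(0, c(n, n, 2))
    bias_full <- twspeech:::ag_value(twspeech:::bias_node(
      p, id, p[["s1.region"]], stage, win, 2, cf$C_r))
    for (w in seq_len(win$nw)) {
      tok <- as.vector(vapply(as.integer(slots[, w]),
                              function(t) (t - 1L) * Ns + seq_len(Ns),
                              integer(Ns)))
      mask[tok, tok] <- TRUE
      for (h in 1:2) {
        br <- ((w - 1) * 2 + h - 1) * M
        bias_arr[tok, tok, h] <- bias_full[(br + 1):(br + M), ]
      }
    }
    tau <- 0.01 + log(1 + exp(p[[paste0(id, "attn.rho")]]$value))
    att <- dense_cosine_attention(Xo, p[[paste0(id, "attn.wqkv")]]$value,
                                  p[[paste0(id, "attn.bqkv")]]$value,
                                  p[[paste0(id, "attn.wproj")]]$value,
                                  p[[paste0(id, "attn.bproj")]]$value,
                                  as.numeric(tau), bias_arr, mask, 2)
    Xo <- Xo + layernorm(att, p[[paste0(id, "ln1.g")]]$value,
                         p[[paste0(id, "ln1.b")]]$value)
    Hm <- lrelu(Xo %*% p[[paste0(id, "mlp.w1")]]$value +
                  matrix(p[[paste0(id, "mlp.b1")]]$value, n,
                         ncol(p[[paste0(id, "mlp.b1")]]$value), byrow = TRUE))
    Hm <- Hm %*% p[[paste0(id, "mlp.w2")]]$value +
      matrix(p[[paste0(id, "mlp.b2")]]$value, n,
             ncol(p[[paste0(id, "mlp.b2")]]$value), byrow = TRUE)
    Xo <- Xo + layernorm(Hm, p[[paste0(id, "ln2.g")]]$value,
                         p[[paste0(id, "ln2.b")]]$value)
  }
  expect_lt(max(abs(got - Xo)), 1e-5)
})
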