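test_that("the 8x8 grid has 64 electrodes on an exact 10 mm lattice", {
  lay <- gen_layout("grid8x8", "left", seed = 12)
  expect_equal(nrow(lay$electrodes), 64)
  expect_true(all(lay$electrodes$kind == "grid"))
  mni <- twspeech:::layout_mni(lay)
  nn <- vapply(seq_len(64), function(i) {
    d <- sqrt(rowSums((mni[-i, , drop = FALSE] -
                         matrix(mni[i, ], 63, 3, byrow = TRUE))^2))
    min(d)
  }, numeric(1))
  expect_equal(nn, rep(10, 64))
})

test_that("sEEG-only layouts stay within the clinical electrode-count range", {
  for (s in c(1, 7, 33)) {
    lay <- gen_layout("seeg_only", "right", seed = s)
    expect_gte(nrow(lay$electrodes), 19)
    expect_lte(nrow(lay$electrodes), 178)
    expect_true(all(lay$electrodes$kind == "sEEG"))
  }
})

test_that("layouts and extras are a pure function of the seed", {
  a <- gen_layout("grid_plus_extras", "left", seed = 5)
  b <- gen_layout("grid_plus_extras", "left", seed = 5)
  expect_identical(a$electrodes, b$electrodes)
  expect_identical(attr(a, "true_mni"), attr(b, "true_mni"))
  c <- gen_layout("grid_plus_extras", "left", seed = 6)
  expect_false(identical(a$electrodes, c$electrodes))
  # unknown-location electrodes sit at the origin with region Unknown
  unk <- a$electrodes$kind == "unknown"
  expect_gte(sum(unk), 1); expect_lte(sum(unk), 11)
  expect_true(all(a$electrodes$roi[unk] == "Unknown"))
  expect_true(all(abs(twspeech:::layout_mni(a)[unk, ]) == 0))
})

test_that("generated trajectories always satisfy the parameter invariants", {
  inv <- gen_speech_trajectories(words = sprintf("w%02d", 1:5), T = 32,
                                 seed = 9)
  for (s in 1:100) {
    p <- gen_trial_params(inv, inv$words[(s - 1) %% 5 + 1], s)
    expect_error(validate_speech_params(p), NA)
    expect_equal(nrow(p), 32)
  }
})

test_that("same-word trials correlate more strongly than different-word trials", {
  inv <- gen_speech_trajectories(words = sprintf("w%02d", 1:6), T = 64,
                                 seed = 2)
  mean_param_pcc <- function(a, b) {
    mean(vapply(1:18, function(i) {
      if (stats::sd(a[, i]) == 0 || stats::sd(b[, i]) == 0) return(1)
      stats::cor(a[, i], b[, i])
    }, numeric(1)))
  }
  same <- diff_ <- c()
  for (s in 1:20) {
    w1 <- inv$words[(s - 1) %% 6 + 1]
    w2 <- inv$words[s %% 6 + 1]
    same <- c(same, mean_param_pcc(gen_trial_params(inv, w1, 2 * s),
                                   gen_trial_params(inv, w1, 2 * s + 1)))
    diff_ <- c(diff_, mean_param_pcc(gen_trial_params(inv, w1, 2 * s),
                                     gen_trial_params(inv, w2, 2 * s + 1)))
  }
  expect_gt(mean(same), mean(diff_))
})

test_that("forward-map weights decay with distance from the parameter sources", {
  atlas <- load_atlas()
  # hand-built layout: a cluster plus one electrode far from everything
  df <- tibble::tibble(
    id = c(sprintf("C%02d", 1:6), "FAR"),
    x = c(rep(-55, 6), -55), y = c(-30, -25, -20, -30, -25, -20, 150),
    z = c(0, 0, 0, 10, 10, 10, 150),
    roi = "Unknown", hemisphere = "unknown", kind = "sEEG")
  df$roi[1:6] <- "superior_temporal"; df$hemisphere[1:6] <- "left"
  lay <- twspeech:::new_layout(df, atlas, "pfar")
  map <- make_forward_map(lay, seed = 3)
  pos <- twspeech:::layout_mni(lay)
  for (i in 1:18) {
    dmin <- vapply(seq_len(nrow(pos)), function(e) {
      min(sqrt(rowSums((map$sources[i, , ] -
                          matrix(pos[e, ], 2, 3, byrow = TRUE))^2)))
    }, numeric(1))
    far <- dmin > 60
    if (any(far)) {
      expect_lt(max(map$weights[far, i]), 0.05 * max(map$weights[, i]))
    }
  }
})

test_that("neural features are deterministic at infinite SNR and geometry-driven", {
  lay <- gen_layout("seeg_only", "left", seed = 4, n_electrodes = 8)
  p <- gen_trial_params(gen_speech_trajectories(words = "w", T = 32, seed = 1),
                        "w", 2)
  map <- make_forward_map(lay, seed = 5)
  a <- gen_neural(p, lay, map = map, snr = Inf, seed = 5)
  b <- gen_neural(p, lay, map = map, snr = Inf, seed = 99) # seed feeds noise only
  expect_identical(a, b)
  n <- gen_neural(p, lay, snr = 10, seed = 5)
  expect_false(identical(a, n))
  expect_identical(n, gen_neural(p, lay, snr = 10, seed = 5))
  # relabeling electrode ids leaves the feature columns untouched
  lay2 <- lay
  lay2$electrodes$id <- paste0("zz_", lay2$electrodes$id)
  expect_identical(gen_neural(p, lay2, map = make_forward_map(lay2, 1)),
                   gen_neural(p, lay, map = make_forward_map(lay, 1)))
})

test_that("a full session has 400 trials with the stated per-task counts", {
  lay <- gen_layout("seeg_only", "left", seed = 10, n_electrodes = 8)
  inv <- gen_speech_trajectories(T = 16, seed = 10) # 50 words
  ses <- gen_session(lay, inv, seed = 10, n_bins = 16)
  expect_equal(nrow(ses$trials), 400)
  counts <- dplyr::count(ses$trials, task)
  expect_equal(counts$n[match(c("AuditoryRepetition", "AuditoryNaming",
                                "SentenceCompletion", "VisualReading",
                                "PictureNaming"), counts$task)],
               c(100, 50, 50, 100, 100))
  # regeneration with the same seed is bit-identical
  ses2 <- gen_session(lay, inv, seed = 10, n_bins = 16)
  expect_identical(ses$features, ses2$features)
  expect_identical(ses$specs, ses2$specs)
})

test_that("session text containers round-trip exactly", {
  lay <- gen_layout("seeg_only", "right", seed = 11, n_electrodes = 6)
  inv <- gen_speech_trajectories(words = sprintf("w%02d", 1:3), T = 16,
                                 seed = 11)
  ses <- suppressWarnings(make_split(gen_session(lay, inv, seed = 11,
                                                 n_bins = 16), 2))
  d <- tempfile()
  session_write(ses, d)
  back <- session_read(d)
  expect_identical(back$features, ses$features)
  expect_identical(back$specs, ses$specs)
  expect_identical(back$params, ses$params)
  expect_equal(back$trials, ses$trials)
  expect_identical(back$layout$electrodes, ses$layout$electrodes)
  expect_equal(back$map$weights, ses$map$weights)
  unlink(d, recursive = TRUE)
})

test_that("a ridge baseline recovers parameters from features at 10 dB SNR", {
  lay <- gen_layout("grid8x8", "left", seed = 21)
  inv <- gen_speech_trajectories(words = sprintf("w%02d", 1:10), T = 64,
                                 seed = 21)
  ses <- suppressWarnings(make_split(gen_session(lay, inv, snr = 10,
                                                 seed = 21), 3))
  lags <- -3:3
  core <- 4:61 # interior frames; lagged predictors are complete there
  lag_expand <- function(X) {
    do.call(cbind, lapply(lags, function(l) {
      Y <- X * 0
      src <- seq_len(nrow(X)) + l
      ok <- src >= 1 & src <= nrow(X)
      Y[ok, ] <- X[src[ok], ]
      Y
    }))[core, ]
  }
  tr <- twspeech:::session_trial_ids(ses, "train")
  te <- twspeech:::session_trial_ids(ses, "test")
  norm_core <- function(p) twspeech:::normalize_params(p)[core, ]
  Xtr <- do.call(rbind, lapply(ses$features[tr], lag_expand))
  Ytr <- do.call(rbind, lapply(ses$params[tr], norm_core))
  beta <- solve(crossprod(Xtr) + diag(ncol(Xtr)), crossprod(Xtr, Ytr))
  Xte <- do.call(rbind, lapply(ses$features[te], lag_expand))
  Yte <- do.call(rbind, lapply(ses$params[te], norm_core))
  pred <- Xte %*% beta
  rec <- vapply(1:18, function(i) stats::cor(pred[, i], Yte[, i]), numeric(1))
  expect_gt(mean(rec), 0.6)
})
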