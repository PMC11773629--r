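tiny_train_setup <- function(n_words = 2, T = 16, N = 4, seed = 1,
                             hemisphere = "left") {
  lay <- gen_layout("seeg_only", hemisphere, seed = seed, n_electrodes = N)
  inv <- gen_speech_trajectories(words = sprintf("tw%02d", seq_len(n_words)),
                                 T = T, seed = seed)
  suppressWarnings(make_split(gen_session(lay, inv, snr = Inf, seed = seed,
                                          n_bins = 32), seed))
}

tiny_train_cfg <- function(epochs = 2, seed = 1) {
  train_config(epochs = epochs, batch = 8, lr = 3e-3, seed = seed,
               reference = "oracle",
               decoder = decoder_config(W = 2, Wt = 2, C = 8, C_out = 8,
                                        stage_heads = c(2, 2, 2),
                                        mlp_ratio = 1, C_r = 2,
                                        bias_hidden = 4))
}

test_that("a full 400-trial session splits 350/50 with 10 test trials per task", {
  lay <- gen_layout("seeg_only", "left", seed = 31, n_electrodes = 4)
  inv <- gen_speech_trajectories(T = 8, seed = 31)
  ses <- gen_session(lay, inv, seed = 31, n_bins = 8)
  sp <- make_split(ses, 5)
  expect_equal(sum(sp$trials$split == "test"), 50)
  expect_equal(sum(sp$trials$split == "train"), 350)
  per_task <- dplyr::count(dplyr::filter(sp$trials, split == "test"), task)
  expect_equal(per_task$n, rep(10, 5))
  sp2 <- make_split(ses, 5)
  expect_identical(sp$trials$split, sp2$trials$split)
  expect_false(identical(sp$trials$split, make_split(ses, 6)$trials$split))
})

test_that("short sessions fall back to proportional test counts with a warning", {
  lay <- gen_layout("seeg_only", "left", seed = 32, n_electrodes = 4)
  inv <- gen_speech_trajectories(words = c("a", "b"), T = 8, seed = 32)
  ses <- gen_session(lay, inv, seed = 32, n_bins = 8)
  expect_warning(sp <- make_split(ses, 1), "proportional")
  expect_equal(sum(sp$trials$split == "test"), 5) # one per task
})

test_that("subject training is deterministic, reduces the loss, and logs it", {
  ses <- tiny_train_setup()
  cfg1 <- tiny_train_cfg(epochs = 4)
  cfg1$log_path <- tempfile(fileext = ".csv")
  f1 <- train_subject(ses, NULL, cfg1)
  loss_log <- readr::read_csv(cfg1$log_path, show_col_types = FALSE)
  expect_equal(nrow(loss_log), 4)
  expect_true(all(c("epoch", "mss", "stoi", "supervision", "reference",
                    "total") %in% names(loss_log)))
  f2 <- train_subject(ses, NULL, tiny_train_cfg(epochs = 4))
  expect_identical(f1$loss, f2$loss)
  expect_lt(utils::tail(f1$loss$total, 1), f1$loss$total[1])
  g <- glance(f1)
  expect_equal(g$epochs, 4)
  td <- tidy(f1)
  expect_true(all(c("epoch", "component", "value") %in% names(td)))
  expect_s3_class(ggplot2::autoplot(f1), "ggplot")
})

test_that("the shared decoder has no participant-indexed parameters", {
  ses <- list(tiny_train_setup(seed = 1), tiny_train_setup(seed = 2))
  fit <- train_multisubject(ses, cfg = tiny_train_cfg(epochs = 1))
  nms <- decoder_param_names(fit$model)
  for (pid in c(ses[[1]]$participant_id, ses[[2]]$participant_id)) {
    expect_false(any(grepl(pid, nms, fixed = TRUE)))
  }
  # names describe only architecture components
  expect_true(all(grepl("^(embed|s[123]|merge[12]|post|up[0-9]|head)\\.",
                        nms)))
})

test_that("multi-subject training on one session reduces to subject training", {
  ses <- tiny_train_setup(seed = 3)
  a <- train_subject(ses, NULL, tiny_train_cfg(epochs = 3))
  b <- train_multisubject(list(ses), list(NULL), tiny_train_cfg(epochs = 3))
  expect_identical(a$loss, b$loss)
  expect_identical(lapply(a$model$params, function(p) p$value),
                   lapply(b$model$params, function(p) p$value))
})

test_that("left and right hemisphere dictionaries both learn during co-training", {
  sesL <- tiny_train_setup(seed = 4, hemisphere = "left")
  sesR <- tiny_train_setup(seed = 5, hemisphere = "right")
  cfg <- tiny_train_cfg(epochs = 1)
  fit <- train_multisubject(list(sesL, sesR), cfg = cfg)
  init <- decoder_init(cfg$decoder,
                       n_regions = sesL$layout$atlas$n_regions,
                       seed = cfg$seed)
  reg <- load_atlas()$regions
  li <- reg$roi_index[reg$hemisphere == "left"] + 1L
  ri <- reg$roi_index[reg$hemisphere == "right"] + 1L
  for (s in 1:3) {
    d <- abs(fit$model$params[[paste0("s", s, ".region")]]$value -
               init$params[[paste0("s", s, ".region")]]$value)
    lrois <- unique(sesL$layout$electrodes$roi_index) + 1L
    rrois <- unique(sesR$layout$electrodes$roi_index) + 1L
    expect_gt(max(d[intersect(li, lrois), ]), 0)
    expect_gt(max(d[intersect(ri, rrois), ]), 0)
    # regions never touched by either subject receive no updates
    untouched <- setdiff(seq_len(nrow(d)), c(lrois, rrois))
    if (length(untouched)) expect_equal(max(d[untouched, ]), 0)
  }
})

test_that("decoding and evaluation work for a trained fit and its controls", {
  ses <- tiny_train_setup(seed = 6)
  fit <- train_subject(ses, NULL, tiny_train_cfg(epochs = 2))
  ids <- twspeech:::session_trial_ids(ses, "test")
  dec <- decode_trials(fit$model, ses$layout, ses$features[ids])
  expect_length(dec, length(ids))
  expect_equal(dim(dec[[1]]), c(16, 18))
  ev <- evaluate_session(fit, ses)
  expect_true(all(c("pcc", "stoi_plus", "mcd") %in% names(ev)))
  evs <- evaluate_session(fit, ses, shuffle = TRUE, shuffle_seed = 2)
  expect_false(identical(ev$pcc, evs$pcc))
})

test_that("cross-validation assigns every session to a held-out fold once", {
  sessions <- lapply(1:3, function(s) tiny_train_setup(seed = s))
  cv <- crossval_unseen(sessions, folds = 3, cfg = tiny_train_cfg(epochs = 1))
  expect_equal(nrow(cv), 3)
  expect_setequal(cv$participant_id,
                  vapply(sessions, function(s) s$participant_id, character(1)))
  expect_setequal(cv$fold, 1:3)
  cv2 <- crossval_unseen(sessions, folds = 3, cfg = tiny_train_cfg(epochs = 1))
  expect_identical(cv$fold, cv2$fold)
  expect_error(crossval_unseen(sessions, folds = 4,
                               cfg = tiny_train_cfg(epochs = 1)),
               "folds")
})

test_that("checkpoint divergence handling restores the last good epoch", {
  ses <- tiny_train_setup(seed = 7)
  cfg <- tiny_train_cfg(epochs = 3)
  cfg$lr <- 1e10 # force blow-up
  expect_warning(fit <- train_subject(ses, NULL, cfg), "non-finite")
  expect_true(all(vapply(fit$model$params,
                         function(p) all(is.finite(p$value)), logical(1))))
})
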