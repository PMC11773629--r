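# Subject-specific and multi-subject neural-decoder training, data splits,
# and cross-validation over synthetic cohorts.

#' Training configuration
#'
#' Adam with learning-rate 5e-4 (beta1 0.9, beta2 0.999) is the reference
#' optimizer setting. Epoch count, batch size and gradient clipping are
#' engineering defaults (unstated in the reference setting). The reference
#' loss uses per-parameter weights 1/range^2 by default, which expresses
#' every parameter's error on a comparable normalized scale; the supervision
#' term is likewise computed on range-normalized frequency tracks inside the
#' training loop (the standalone [supervision_loss()] stays in Hz^2).
#'
#' @param epochs Training epochs.
#' @param batch Trials per gradient step.
#' @param lr,beta1,beta2 Adam settings.
#' @param seed Seed for initialization and batch order.
#' @param weights A [loss_weights()]; defaults to range-normalized
#'   per-parameter weights.
#' @param decoder A [decoder_config()].
#' @param clip Gradient-norm clip (default 1).
#' @param reference `"encoder"` (parameters from the trained speech encoder,
#'   the two-step pipeline) or `"oracle"` (the generator's true parameters;
#'   synthetic-data shortcut for mechanism tests).
#' @param log_path Optional CSV path; per-epoch loss components are written
#'   there as training progresses.
#' @param verbose Print epoch losses.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 30, batch = 8, lr = 5e-4, beta1 = 0.9,
                         beta2 = 0.999, seed = 1,
                         weights = NULL, decoder = decoder_config(),
                         clip = 1, reference = c("encoder", "oracle"),
                         log_path = NULL, verbose = FALSE) {
  if (is.null(weights)) {
    r <- speech_param_ranges()
    weights <- loss_weights(per_param = 1 / (r[, "hi"] - r[, "lo"])^2)
  }
  stopifnot(lr > 0)
  structure(list(epochs = epochs, batch = batch, lr = lr, beta1 = beta1,
                 beta2 = beta2, seed = seed, weights = weights,
                 decoder = decoder, clip = clip,
                 reference = match.arg(reference), log_path = log_path,
                 verbose = verbose),
            class = "train_config")
}

#' Split a session into training and held-out test trials
#'
#' For a full 400-trial session, 10 randomly selected trials per task are
#' held out (50 test / 350 train). Shorter sessions fall back to the same
#' proportion (an eighth per task, at least one), with a warning.
#'
#' @param session A `tw_session`.
#' @param seed Split seed.
#' @return The session with a `split` column (`"train"`/`"test"`) added to
#'   its trial table.
#' @export
make_split <- function(session, seed = 1) {
  trials <- session$trials
  full <- nrow(trials) == 400
  if (!full) {
    warning("session has ", nrow(trials),
            " trials (not 400); using proportional test counts")
  }
  split <- rep("train", nrow(trials))
  with_seed(seed, {
    for (task in unique(trials$task)) {
      rows <- which(trials$task == task)
      n_test <- if (full) 10L else max(1L, round(length(rows) / 8))
      split[sample(rows, n_test)] <- "test"
    }
  })
  session$trials$split <- split
  session
}

session_trial_ids <- function(session, which = c("train", "test", "all")) {
  which <- match.arg(which)
  if (which == "all" || is.null(session$trials$split)) {
    return(session$trials$trial_id)
  }
  session$trials$trial_id[session$trials$split == which]
}

# range-normalized supervision term on f0, f1..f4; mask NaN = no supervision
sup_norm_node <- function(P, ref_freqs_norm) {
  mask <- matrix(as.numeric(is.finite(ref_freqs_norm)), nrow(ref_freqs_norm))
  ref0 <- ifelse(is.finite(ref_freqs_norm), ref_freqs_norm, 0)
  r <- speech_param_ranges()[1:5, ]
  lo <- matrix(r[, "lo"], 1)
  inv_span <- matrix(1 / (r[, "hi"] - r[, "lo"]), 1)
  pred_n <- ag_mul(ag_sub(ag_slice_cols(P, 1:5), lo), inv_span)
  d <- ag_mul(ag_sub(pred_n, ref0), mask)
  ag_scale(ag_sum(ag_square(d)), 1 / max(1, sum(mask)))
}

# per-subject prepared training state (canonical electrode order throughout)
prepare_subject <- function(session, speech_model, cfg) {
  ord <- layout_canonical_order(session$layout)
  lay <- permute_layout(session$layout, ord)
  T <- nrow(session$specs[[1]])
  feats <- lapply(session$features, function(f) f[, ord, drop = FALSE])
  ids <- session_trial_ids(session, "train")
  n <- length(session$specs)
  if (cfg$reference == "oracle" || is.null(speech_model)) {
    refs <- session$params
  } else {
    S <- do.call(rbind, session$specs)
    Pv <- ag_value(encoder_forward(speech_model$encoder, ag_const(S),
                                   as.integer(n), T))
    refs <- lapply(seq_len(n), function(i) Pv[((i - 1) * T + 1):(i * T), ])
    names(refs) <- names(session$specs)
  }
  # supervision: the generator's true pitch/formant tracks, NaN on unvoiced
  r <- speech_param_ranges()[1:5, ]
  sup <- lapply(session$params, function(p) {
    f <- sweep(sweep(p[, 1:5, drop = FALSE], 2, r[, "lo"]), 2,
               r[, "hi"] - r[, "lo"], "/")
    f[p[, "alpha"] < 0.5, ] <- NaN
    f
  })
  list(layout = lay, T = T, feats = feats, refs = refs, sup = sup,
       specs = session$specs, train_ids = ids,
       n_bins = session$n_bins, fmax = session$fmax,
       participant_id = session$participant_id)
}

batch_loss_node <- function(model, plan, sub, ids, mel, octave, w) {
  B <- length(ids)
  T <- sub$T
  patches <- build_patches(sub$feats[ids], model$config$W)
  P <- decoder_forward_node(model, plan, patches)
  R <- synth_node(P, n_bins = sub$n_bins, fmax = sub$fmax)
  S <- do.call(rbind, sub$specs[ids])
  mss <- mss_node(R, ag_const(S), mel)
  stois <- lapply(seq_len(B), function(b) {
    rows <- as.integer(((b - 1) * T + 1):(b * T))
    stoi_node(ag_gather_rows(R, rows), sub$specs[[ids[b]]], octave)
  })
  stoi <- ag_mean(ag_cbind(stois))
  ref <- ag_scale(reference_node(P, ag_const(do.call(rbind, sub$refs[ids])),
                                 w$per_param), 1 / (B * T))
  sup <- sup_norm_node(P, do.call(rbind, sub$sup[ids]))
  total <- ag_add(ag_add(mss, ag_scale(stoi, -w$lambda_stoi)),
                  ag_add(ag_scale(sup, w$lambda_sup),
                         ag_scale(ref, w$lambda_ref)))
  list(total = total, parts = c(mss = ag_value(mss)[1],
                                stoi = -ag_value(stoi)[1],
                                supervision = ag_value(sup)[1],
                                reference = ag_value(ref)[1]))
}

train_core <- function(subs, cfg, atlas_regions) {
  model <- decoder_init(cfg$decoder, n_regions = atlas_regions,
                        seed = cfg$seed)
  opt <- adam_init(model$params, lr = cfg$lr, beta1 = cfg$beta1,
                   beta2 = cfg$beta2)
  mel <- mel_filterbank(subs[[1]]$n_bins, subs[[1]]$fmax)
  octave <- third_octave_bands(subs[[1]]$n_bins, subs[[1]]$fmax)
  plans <- new.env(parent = emptyenv())
  get_plan <- function(si, B) {
    key <- paste0(si, ".", B)
    if (is.null(plans[[key]])) {
      plans[[key]] <- decoder_plan(cfg$decoder, subs[[si]]$layout,
                                   subs[[si]]$T, B)
    }
    plans[[key]]
  }
  log <- vector("list", cfg$epochs)
  w <- cfg$weights
  for (ep in seq_len(cfg$epochs)) {
    # round-robin interleaving of per-subject mini-batches
    chunks <- list()
    for (si in seq_along(subs)) {
      ids <- with_seed(cfg$seed * 131 + ep * 17 + si,
                       sample(subs[[si]]$train_ids))
      bs <- split(ids, ceiling(seq_along(ids) / cfg$batch))
      for (k in seq_along(bs)) {
        chunks[[length(chunks) + 1]] <- list(si = si, ids = bs[[k]], k = k)
      }
    }
    chunks <- chunks[order(vapply(chunks, function(ch) ch$k, numeric(1)))]
    snapshot <- lapply(model$params, function(p) p$value)
    acc <- c(mss = 0, stoi = 0, supervision = 0, reference = 0, total = 0)
    nb <- 0
    diverged <- FALSE
    for (ch in chunks) {
      ag_zero_grads(model$params)
      ag_tape_start()
      bl <- batch_loss_node(model, get_plan(ch$si, length(ch$ids)),
                            subs[[ch$si]], ch$ids, mel, octave, w)
      tv <- ag_value(bl$total)[1]
      if (!is.finite(tv)) {
        ag_tape_stop()
        for (nm in names(model$params)) model$params[[nm]]$value <- snapshot[[nm]]
        warning("non-finite loss at epoch ", ep,
                "; restored last epoch's parameters")
        diverged <- TRUE
        break
      }
      ag_backward(bl$total)
      ag_tape_stop()
      opt <- adam_step(opt, clip = cfg$clip)
      acc <- acc + c(bl$parts, total = tv)
      nb <- nb + 1
    }
    if (diverged) {
      log <- log[seq_len(ep - 1)]
      break
    }
    log[[ep]] <- tibble::tibble(epoch = ep, !!!as.list(acc / nb))
    if (!is.null(cfg$log_path)) {
      readr::write_csv(dplyr::bind_rows(log[seq_len(ep)]), cfg$log_path)
    }
    if (cfg$verbose) {
      message(sprintf("epoch %d/%d total %.4f (mss %.4f stoi %.3f)", ep,
                      cfg$epochs, acc["total"] / nb, acc["mss"] / nb,
                      acc["stoi"] / nb))
    }
  }
  structure(list(model = model, loss = dplyr::bind_rows(log), config = cfg,
                 participants = vapply(subs, function(s) s$participant_id,
                                       character(1))),
            class = "tw_fit")
}

#' Train a subject-specific neural decoder
#'
#' Second step of the two-step pipeline: with the participant's speech
#' encoder fixed, the decoder is trained on the session's training trials to
#' minimize the composite objective (multi-scale spectral + intelligibility
#' + supervision + reference loss). Deterministic given the config seed.
#'
#' @param session A `tw_session` with a split (see [make_split()]; one is
#'   made with the config seed if absent).
#' @param speech_model The participant's `speech_model` from
#'   [train_speech_autoencoder()] (may be `NULL` with
#'   `reference = "oracle"`).
#' @param cfg A [train_config()].
#' @return A `tw_fit`: the trained `tw_decoder` plus the per-epoch loss
#'   table.
#' @export
train_subject <- function(session, speech_model = NULL, cfg = train_config()) {
  train_multisubject(list(session), list(speech_model), cfg)
}

#' Train one shared decoder on multiple participants
#'
#' A single decoder (no subject-specific layers — verifiable via
#' [decoder_param_names()]) is trained on several sessions whose layouts may
#' differ arbitrarily in electrode count, placement and hemisphere. Batches
#' are round-robin per-subject mini-batches; hemisphere-specific region
#' embeddings receive gradients only from same-hemisphere electrodes because
#' the hemispheres occupy disjoint region indices. With a single session
#' this reduces exactly to [train_subject()].
#'
#' @param sessions List of `tw_session`s (same atlas).
#' @param speech_models List of per-participant `speech_model`s (or `NULL`s
#'   with `reference = "oracle"`).
#' @param cfg A [train_config()].
#' @return A `tw_fit`.
#' @export
train_multisubject <- function(sessions, speech_models = NULL,
                               cfg = train_config()) {
  stopifnot(length(sessions) >= 1)
  speech_models <- speech_models %||% vector("list", length(sessions))
  nr <- vapply(sessions, function(s) s$layout$atlas$n_regions, numeric(1))
  if (length(unique(nr)) != 1) {
    rlang::abort("sessions use different atlases; a shared decoder needs one atlas")
  }
  sessions <- lapply(sessions, function(s) {
    if (is.null(s$trials$split)) make_split(s, cfg$seed) else s
  })
  subs <- purrr::map2(sessions, speech_models,
                      function(s, m) prepare_subject(s, m, cfg))
  train_core(subs, cfg, atlas_regions = nr[1])
}

#' Decode a set of trials in one batched pass
#'
#' @param model A `tw_decoder`.
#' @param layout The participant's layout.
#' @param features List of T x N feature matrices (layout column order).
#' @return List of T x 18 parameter matrices.
#' @export
decode_trials <- function(model, layout, features) {
  ord <- layout_canonical_order(layout)
  lay <- permute_layout(layout, ord)
  T <- nrow(features[[1]])
  plan <- decoder_plan(model$config, lay, T, length(features))
  patches <- build_patches(lapply(features, function(f) f[, ord, drop = FALSE]),
                           model$config$W)
  out <- ag_value(decoder_forward_node(model, plan, patches))
  lapply(seq_along(features), function(b) {
    m <- out[((b - 1) * T + 1):(b * T), , drop = FALSE]
    colnames(m) <- speech_param_names()
    m
  })
}

#' Evaluate a decoder on a session's held-out trials
#'
#' Decodes the requested trials, synthesizes spectrograms from the predicted
#' parameters, and scores them against the session's true spectrograms with
#' PCC, STOI+ and MCD. Optionally the inputs are temporally shuffled first
#' (the chance-level control).
#'
#' @param model A `tw_decoder` (or a `tw_fit`).
#' @param session A `tw_session`.
#' @param which `"test"` (default), `"train"` or `"all"`.
#' @param shuffle Shuffle inputs temporally (seeded) before decoding.
#' @param shuffle_seed Seed for the shuffles.
#' @return Evaluation tibble from [evaluate_participant()].
#' @export
evaluate_session <- function(model, session, which = "test", shuffle = FALSE,
                             shuffle_seed = 1) {
  if (inherits(model, "tw_fit")) model <- model$model
  ids <- session_trial_ids(session, which)
  feats <- session$features[ids]
  if (shuffle) {
    feats <- lapply(seq_along(feats), function(i) {
      shuffle_control(feats[[i]], shuffle_seed + i)
    })
  }
  dec <- decode_trials(model, session$layout, feats)
  specs <- lapply(dec, function(p) {
    synthesize(p, n_bins = session$n_bins, fmax = session$fmax)
  })
  evaluate_participant(specs, session$specs[ids],
                       participant_id = session$participant_id)
}

#' Leave-fold-out cross-validation over participants
#'
#' Splits participants into folds; each fold's decoder is trained on the
#' remaining participants and evaluated on the held-out ones, whose layouts
#' were never seen during training.
#'
#' @param sessions List of `tw_session`s.
#' @param folds Number of folds (must not exceed the session count).
#' @param cfg A [train_config()].
#' @param speech_models Optional list of per-participant speech models.
#' @return Tibble with one row per held-out participant: fold, metrics, and
#'   the shuffled-input control PCC.
#' @export
crossval_unseen <- function(sessions, folds, cfg = train_config(),
                            speech_models = NULL) {
  n <- length(sessions)
  if (folds > n) rlang::abort("more folds than sessions")
  speech_models <- speech_models %||% vector("list", n)
  fold_of <- with_seed(cfg$seed, sample(rep(seq_len(folds), length.out = n)))
  out <- list()
  for (f in seq_len(folds)) {
    tr <- which(fold_of != f)
    fit <- train_multisubject(sessions[tr], speech_models[tr], cfg)
    for (i in which(fold_of == f)) {
      s <- sessions[[i]]
      if (is.null(s$trials$split)) s <- make_split(s, cfg$seed)
      ev <- evaluate_session(fit$model, s)
      evs <- evaluate_session(fit$model, s, shuffle = TRUE)
      out[[length(out) + 1]] <- tibble::tibble(
        fold = f, participant_id = s$participant_id, pcc = ev$pcc,
        stoi_plus = ev$stoi_plus, mcd = ev$mcd,
        pcc_shuffled = evs$pcc)
    }
  }
  dplyr::bind_rows(out)
}

# ---- broom-style accessors ---------------------------------------------------

#' Per-epoch loss components of a decoder fit
#' @param x A `tw_fit`.
#' @param ... Unused.
#' @return Long tibble: epoch, component, value.
#' @export
tidy.tw_fit <- function(x, ...) {
  tidyr::pivot_longer(x$loss, -"epoch", names_to = "component",
                      values_to = "value")
}

#' One-row summary of a decoder fit
#' @param x A `tw_fit`.
#' @param ... Unused.
#' @return Tibble with participants, epochs, final losses, parameter count.
#' @export
glance.tw_fit <- function(x, ...) {
  fin <- utils::tail(x$loss, 1)
  tibble::tibble(participants = paste(x$participants, collapse = ","),
                 epochs = nrow(x$loss),
                 total = fin$total, mss = fin$mss, stoi = fin$stoi,
                 n_params = sum(vapply(x$model$params,
                                       function(p) length(p$value), numeric(1))))
}

#' Training-loss curves of a decoder fit
#' @param object A `tw_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tw_fit <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL)
}

#' @export
print.tw_fit <- function(x, ...) {
  cat("<tw_fit> participants: ", paste(x$participants, collapse = ", "),
      "; ", nrow(x$loss), " epochs, final total loss ",
      formatC(utils::tail(x$loss$total, 1), digits = 4, format = "f"),
      "\n", sep = "")
  invisible(x)
}
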