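# Synthetic participants: electrode layouts placed in MNI space, per-word
# speech-parameter trajectories, and neural features generated from the
# trajectories through a known forward map (spatial mixing + temporal
# convolution + noise). Every other module is testable against this known
# ground truth without any patient data.

`%||%` <- function(a, b) if (is.null(a)) b else a

nearest_roi <- function(pts, atlas, hemisphere) {
  cand <- dplyr::filter(atlas$regions, .data$hemisphere == !!hemisphere)
  cents <- as.matrix(cand[, c("x", "y", "z")])
  idx <- apply(pts, 1, function(p) {
    which.min(colSums((t(cents) - p)^2))
  })
  cand$roi[idx]
}

#' Generate a synthetic electrode layout
#'
#' Three families mirror the clinical electrode configurations:
#' `grid8x8` is a 64-electrode 8 x 8 lattice with exact 10 mm spacing on a
#' lateral (perisylvian-like) plane of MNI space; `grid_plus_extras` adds
#' seeded counts of strip electrodes (on-surface lines), depth electrodes
#' (inward linear trajectories) and 1-11 unknown-location electrodes (MNI
#' fixed at the origin, region Unknown); `seeg_only` places only depth
#' shafts, with a total electrode count drawn in 19-178 unless given.
#' Regions are assigned by proximity to the atlas centroids. Unknown
#' electrodes keep a hidden true position (used only by the neural forward
#' map) in `attr(, "true_mni")`.
#'
#' @param kind `"grid8x8"`, `"grid_plus_extras"` or `"seeg_only"`.
#' @param hemisphere `"left"` or `"right"`.
#' @param seed Integer seed; layouts are a pure function of it.
#' @param n_electrodes Optional electrode count for `seeg_only`.
#' @param atlas A `roi_atlas`.
#' @param participant_id Participant label.
#' @return An `electrode_layout` (plus hidden `true_mni` attribute).
#' @export
gen_layout <- function(kind = c("grid8x8", "grid_plus_extras", "seeg_only"),
                       hemisphere = c("left", "right"), seed = 1,
                       n_electrodes = NULL, atlas = load_atlas(),
                       participant_id = paste0("sim", seed)) {
  kind <- match.arg(kind)
  hemisphere <- match.arg(hemisphere)
  sgn <- if (hemisphere == "left") -1 else 1
  build <- function() {
    rows <- list()
    true_pos <- list()
    add <- function(id, pos, kd, hidden = NULL) {
      rows[[length(rows) + 1]] <<- tibble::tibble(
        id = id, x = pos[1], y = pos[2], z = pos[3], kind = kd)
      true_pos[[length(true_pos) + 1]] <<- hidden %||% pos
    }
    if (kind != "seeg_only") {
      for (i in 1:8) for (j in 1:8) {
        add(sprintf("G%02d", (i - 1) * 8 + j),
            c(sgn * 55, -55 + 10 * (i - 1), -25 + 10 * (j - 1)), "grid")
      }
    }
    if (kind == "grid_plus_extras") {
      n_strip <- sample(1:19, 1)
      dirs <- list(c(0, 1, 0), c(0, 0, 1), c(0, 1, 1) / sqrt(2))
      start <- c(sgn * 55, stats::runif(1, -70, 10), stats::runif(1, -30, 40))
      dir <- dirs[[sample(3, 1)]]
      for (s in seq_len(n_strip)) {
        add(sprintf("ST%02d", s), start + 10 * (s - 1) * dir, "strip")
      }
      n_depth <- sample(1:21, 1)
      entry <- c(sgn * 55, stats::runif(1, -60, 0), stats::runif(1, -20, 40))
      ddir <- c(-sgn, stats::rnorm(2, 0, 0.3))
      ddir <- ddir / sqrt(sum(ddir^2))
      for (s in seq_len(n_depth)) {
        add(sprintf("D%02d", s), entry + 6 * (s - 1) * ddir, "depth")
      }
      n_unk <- sample(1:11, 1)
      for (s in seq_len(n_unk)) {
        hidden <- c(sgn * stats::runif(1, 30, 60), stats::runif(1, -70, 20),
                    stats::runif(1, -30, 50))
        add(sprintf("U%02d", s), c(0, 0, 0), "unknown", hidden = hidden)
      }
    }
    if (kind == "seeg_only") {
      n <- n_electrodes %||% sample(19:178, 1)
      placed <- 0
      shaft <- 0
      while (placed < n) {
        shaft <- shaft + 1
        k <- min(sample(8:16, 1), n - placed)
        entry <- c(sgn * 60, stats::runif(1, -70, 20), stats::runif(1, -30, 50))
        ddir <- c(-sgn, stats::rnorm(2, 0, 0.4))
        ddir <- ddir / sqrt(sum(ddir^2))
        for (s in seq_len(k)) {
          add(sprintf("S%02d-%02d", shaft, s), entry + 5 * (s - 1) * ddir, "sEEG")
          placed <- placed + 1
        }
      }
    }
    df <- dplyr::bind_rows(rows)
    known <- df$kind != "unknown"
    df$hemisphere <- ifelse(known, hemisphere, "unknown")
    df$roi <- "Unknown"
    if (any(known)) {
      df$roi[known] <- nearest_roi(as.matrix(df[known, c("x", "y", "z")]),
                                   atlas, hemisphere)
    }
    list(df = df, true_mni = do.call(rbind, true_pos))
  }
  out <- with_seed(seed, build())
  layout <- new_layout(out$df[, c("id", "x", "y", "z", "roi", "hemisphere",
                                  "kind")],
                       atlas, participant_id)
  attr(layout, "true_mni") <- out$true_mni
  layout
}

layout_true_mni <- function(layout) {
  attr(layout, "true_mni") %||% layout_mni(layout)
}

smooth_curve <- function(T, k = 5, lo, hi) {
  ctrl <- stats::runif(k, lo, hi)
  stats::spline(seq(0, 1, length.out = k), ctrl,
                xout = seq(0, 1, length.out = T))$y
}

#' Generate per-word speech-parameter templates
#'
#' Each of the `length(words)` words receives smooth random trajectories for
#' the 18 parameters (cubic-spline interpolation of control points inside
#' the physiological ranges of [speech_param_ranges()]). The voicing mix
#' `alpha` is a squashed smooth curve creating voiced/unvoiced stretches and
#' loudness `L` is a raised-cosine word-production bump. Trial realizations
#' add small smooth jitter to a template, so trials of the same word stay
#' more similar than trials of different words.
#'
#' @param words Character vector of word labels (default 50 synthetic words).
#' @param T Frames per trial (default 64).
#' @param seed Integer seed.
#' @return A `speech_inventory`: list with `words`, `templates` (named list
#'   of T x 18 matrices), `T` and `jitter_sd`.
#' @export
gen_speech_trajectories <- function(words = sprintf("word%02d", 1:50),
                                    T = 64, seed = 1) {
  r <- speech_param_ranges()
  nm <- speech_param_names()
  make_word <- function() {
    P <- matrix(0, T, 18, dimnames = list(NULL, nm))
    for (i in seq_len(18)) {
      lo <- r[i, "lo"]; hi <- r[i, "hi"]; span <- hi - lo
      P[, i] <- pmin(pmax(smooth_curve(T, 5, lo + 0.1 * span, hi - 0.1 * span),
                          lo), hi)
    }
    P[, "alpha"] <- stats::plogis(3 * smooth_curve(T, 5, -2, 2))
    tt <- (seq_len(T) - 0.5) / T
    ce <- stats::runif(1, 0.35, 0.65)
    wd <- stats::runif(1, 0.35, 0.55)
    bump <- ifelse(abs(tt - ce) <= wd / 2,
                   0.5 * (1 + cos(2 * pi * (tt - ce) / wd)), 0)
    P[, "L"] <- 0.05 + 0.9 * bump
    P
  }
  templates <- with_seed(seed, {
    out <- lapply(words, function(w) make_word())
    names(out) <- words
    out
  })
  structure(list(words = words, templates = templates, T = T,
                 jitter_sd = 0.04, seed = seed),
            class = "speech_inventory")
}

#' Realize one trial's speech parameters for a word
#'
#' Template plus smooth seeded jitter (sd `jitter_sd` of each parameter's
#' range), clipped back into range; always satisfies
#' [validate_speech_params()].
#'
#' @param inventory A `speech_inventory`.
#' @param word One of its words.
#' @param seed Trial seed.
#' @return T x 18 parameter matrix.
#' @export
gen_trial_params <- function(inventory, word, seed) {
  tmpl <- inventory$templates[[word]]
  if (is.null(tmpl)) rlang::abort(paste0("unknown word '", word, "'"))
  r <- speech_param_ranges()
  T <- nrow(tmpl)
  jit <- with_seed(seed, {
    vapply(seq_len(18), function(i) {
      span <- r[i, "hi"] - r[i, "lo"]
      smooth_curve(T, 5, -inventory$jitter_sd * span,
                   inventory$jitter_sd * span)
    }, numeric(T))
  })
  P <- tmpl + jit
  for (i in seq_len(18)) P[, i] <- pmin(pmax(P[, i], r[i, "lo"]), r[i, "hi"])
  P
}

#' Population-level neural code for multi-subject simulations
#'
#' Samples, once per cohort, two cortical source points per speech parameter
#' near randomly chosen atlas region centroids (canonical left-hemisphere
#' coordinates; the forward map uses each source and its x-mirrored twin, a
#' bilateral representation), plus the shared temporal kernels. Subjects
#' built on the same population code share their neural organization and
#' differ only in where their electrodes sample it — the structure a shared
#' anatomy-aware decoder can exploit and transfer to unseen subjects.
#'
#' @param seed Cohort seed.
#' @param atlas A `roi_atlas`.
#' @param sigma Spatial decay scale in mm (default 20).
#' @return A `population_code` list (`sources` 18 x 2 x 3, `kernels` 5 x 18,
#'   `sigma`).
#' @export
population_code <- function(seed = 1, atlas = load_atlas(), sigma = 20) {
  left <- dplyr::filter(atlas$regions, .data$hemisphere == "left")
  with_seed(seed, {
    sources <- array(0, c(18, 2, 3))
    for (i in 1:18) for (s in 1:2) {
      c0 <- as.numeric(left[sample(nrow(left), 1), c("x", "y", "z")])
      sources[i, s, ] <- c0 + stats::rnorm(3, 0, 8)
    }
    K <- matrix(stats::rnorm(5 * 18), 5, 18)
    K <- sweep(K, 2, sqrt(colSums(K^2)), "/")
    structure(list(sources = sources, kernels = K, sigma = sigma,
                   seed = seed),
              class = "population_code")
  })
}

#' Build the neural forward map of a synthetic participant
#'
#' Each of the 18 speech parameters is assigned two cortical source points
#' inside the participant's electrode bounding box; an electrode picks up a
#' parameter with weight `sum_s exp(-d(e, s)^2 / (2 sigma^2))` (sigma 20 mm),
#' so electrodes far from every source carry essentially no signal. Each
#' parameter is temporally convolved with a random length-5 kernel (neural
#' lead/lag) before mixing. The returned map is the ground truth that
#' decoder-recovery tests measure against.
#'
#' @param layout An `electrode_layout` (hidden true positions are used for
#'   unknown-location electrodes).
#' @param seed Integer seed (subject-level map; ignored when `code` given).
#' @param sigma Spatial decay scale in mm (default 20).
#' @param code Optional [population_code()]; when given, sources and kernels
#'   come from the shared code (each source contributes together with its
#'   x-mirrored twin) instead of being drawn per subject.
#' @return A `forward_map`: list with `sources` (18 x 2 x 3), `weights`
#'   (N x 18), `kernels` (5 x 18), `sigma`.
#' @export
make_forward_map <- function(layout, seed = 1, sigma = 20, code = NULL) {
  pos <- layout_true_mni(layout)
  if (!is.null(code)) {
    W <- matrix(0, nrow(pos), 18)
    for (i in 1:18) for (s in 1:2) {
      src <- code$sources[i, s, ]
      for (m in list(src, src * c(-1, 1, 1))) {
        d2 <- rowSums((pos - matrix(m, nrow(pos), 3, byrow = TRUE))^2)
        W[, i] <- W[, i] + exp(-d2 / (2 * code$sigma^2))
      }
    }
    return(structure(list(sources = code$sources, weights = W,
                          kernels = code$kernels, sigma = code$sigma,
                          seed = code$seed),
                     class = "forward_map"))
  }
  with_seed(seed, {
    lohi <- apply(pos, 2, range)
    sources <- array(0, c(18, 2, 3))
    # sources live in the sampled cortex patch: uniform in the electrode
    # bounding box but within 25 mm of some electrode, so each parameter is
    # observable somewhere
    draw_source <- function() {
      for (try in 1:100) {
        cand <- stats::runif(3, lohi[1, ], lohi[2, ])
        d <- sqrt(rowSums(sweep(pos, 2, cand)^2))
        if (min(d) <= 25) return(cand)
      }
      pos[sample(nrow(pos), 1), ] + stats::rnorm(3, 0, 5)
    }
    for (i in 1:18) for (s in 1:2) {
      sources[i, s, ] <- draw_source()
    }
    W <- matrix(0, nrow(pos), 18)
    for (i in 1:18) {
      for (s in 1:2) {
        d2 <- rowSums((pos - matrix(sources[i, s, ], nrow(pos), 3,
                                    byrow = TRUE))^2)
        W[, i] <- W[, i] + exp(-d2 / (2 * sigma^2))
      }
    }
    K <- matrix(stats::rnorm(5 * 18), 5, 18)
    K <- sweep(K, 2, sqrt(colSums(K^2)), "/")
    structure(list(sources = sources, weights = W, kernels = K, sigma = sigma,
                   seed = seed),
              class = "forward_map")
  })
}

# normalize parameters to [-1, 1] by their ranges
normalize_params <- function(P) {
  r <- speech_param_ranges()
  mid <- (r[, "hi"] + r[, "lo"]) / 2
  half <- (r[, "hi"] - r[, "lo"]) / 2
  sweep(sweep(P, 2, mid), 2, half, "/")
}

#' Generate neural features from speech parameters
#'
#' Applies the participant's forward map: normalized parameter trajectories
#' are convolved with the map's temporal kernels, spatially mixed by the
#' distance-decay weights, and Gaussian noise is added at the requested SNR
#' (`Inf` = noiseless, deterministic given the map).
#'
#' @param params T x 18 speech parameters.
#' @param layout The participant's `electrode_layout`.
#' @param map A `forward_map` (built from `layout` if `NULL`).
#' @param snr Signal-to-noise ratio in dB (default `Inf`).
#' @param seed Seed for the noise draw (and map, if built here).
#' @return T x N feature matrix (column order = layout order).
#' @export
gen_neural <- function(params, layout, map = NULL, snr = Inf, seed = 1) {
  map <- map %||% make_forward_map(layout, seed)
  Z <- normalize_params(params)
  Zc <- vapply(seq_len(18), function(i) {
    v <- stats::filter(Z[, i], map$kernels[, i], sides = 2)
    v[!is.finite(v)] <- 0
    as.numeric(v)
  }, numeric(nrow(Z)))
  X <- Zc %*% t(map$weights)
  if (is.finite(snr)) {
    noise_sd <- stats::sd(X) / 10^(snr / 20)
    X <- X + with_seed(seed, matrix(stats::rnorm(length(X), 0, noise_sd),
                                    nrow(X)))
  }
  # features mirror the preprocessed representation: z-scored per electrode
  zscore_channels(X)
}

TASK_PLAN <- c(AuditoryRepetition = 2, AuditoryNaming = 1,
               SentenceCompletion = 1, VisualReading = 2, PictureNaming = 2)

#' Generate a full synthetic word-production session
#'
#' Builds the paired dataset the training pipeline consumes: for each word,
#' 8 trials across the five tasks (twice in auditory repetition, visual
#' reading and picture naming; once in auditory naming and sentence
#' completion) — 400 trials for the full 50-word inventory. Each trial has
#' realized speech parameters, the synthesized spectrogram, and neural
#' features from the participant's forward map.
#'
#' @param layout The participant's `electrode_layout`.
#' @param inventory A `speech_inventory` (built here if `NULL`).
#' @param words Words to include (default: all of the inventory).
#' @param snr Neural SNR in dB (default `Inf`).
#' @param seed Session seed (drives trial jitter, noise, and the forward
#'   map unless one is given).
#' @param map Optional `forward_map`.
#' @param code Optional [population_code()] shared across a cohort; used to
#'   build the forward map when `map` is `NULL`.
#' @param frame_rate Frame rate in Hz (default 125).
#' @param n_bins,fmax Spectrogram geometry.
#' @return A `tw_session`: list with `participant_id`, `layout`, `trials`
#'   (tibble: trial_id, task, word), `features`, `specs`, `params` (lists of
#'   matrices), `map`, `frame_rate`.
#' @export
gen_session <- function(layout, inventory = NULL, words = NULL, snr = Inf,
                        seed = 1, map = NULL, code = NULL, frame_rate = 125,
                        n_bins = 128, fmax = 8000) {
  inventory <- inventory %||% gen_speech_trajectories(seed = seed)
  words <- words %||% inventory$words
  stopifnot(all(words %in% inventory$words))
  map <- map %||% make_forward_map(layout, seed, code = code)
  trials <- tidyr::expand_grid(word = words,
                               task = rep(names(TASK_PLAN), TASK_PLAN))
  trials <- dplyr::arrange(trials, .data$word, .data$task)
  trials$trial_id <- sprintf("t%03d", seq_len(nrow(trials)))
  params <- vector("list", nrow(trials))
  specs <- vector("list", nrow(trials))
  features <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    params[[i]] <- gen_trial_params(inventory, trials$word[i], seed * 1000 + i)
    specs[[i]] <- synthesize(params[[i]], n_bins = n_bins, fmax = fmax)
    features[[i]] <- gen_neural(params[[i]], layout, map = map, snr = snr,
                                seed = seed * 1000 + i)
  }
  names(params) <- names(specs) <- names(features) <- trials$trial_id
  structure(list(participant_id = layout$participant_id, layout = layout,
                 trials = trials[, c("trial_id", "task", "word")],
                 features = features, specs = specs, params = params,
                 map = map, frame_rate = frame_rate, n_bins = n_bins,
                 fmax = fmax, seed = seed),
            class = "tw_session")
}

#' @export
print.tw_session <- function(x, ...) {
  cat("<tw_session> participant '", x$participant_id, "', ",
      nrow(x$trials), " trials, ", n_electrodes(x$layout), " electrodes, T=",
      nrow(x$specs[[1]]), " frames\n", sep = "")
  print(dplyr::count(x$trials, .data$task))
  invisible(x)
}
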