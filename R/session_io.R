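# Plain-text session container: a directory with layout.tsv, manifest.json
# and one TSV per array family (features / spectrograms / parameters), rows
# keyed by trial id. Values are written in shortest round-trip notation, so
# a write/read cycle reproduces every array exactly.

# values serialized with 17 significant digits, which round-trips doubles
# exactly through the text container
array_table <- function(mats, trials) {
  wide <- do.call(rbind, mats)
  chr <- apply(wide, 2, function(col) sprintf("%.17g", col))
  df <- tibble::as_tibble(chr, .name_repair = ~ sprintf("v%04d", seq_along(.x)))
  df <- dplyr::mutate(df,
                      trial_id = rep(trials, vapply(mats, nrow, integer(1))),
                      .before = 1)
  df
}

table_arrays <- function(df, colnames_ = NULL) {
  ids <- unique(df$trial_id)
  m <- matrix(as.numeric(as.matrix(df[, -1])), nrow = nrow(df))
  out <- lapply(ids, function(id) {
    x <- m[df$trial_id == id, , drop = FALSE]
    colnames(x) <- colnames_
    x
  })
  names(out) <- ids
  out
}

#' Write / read a session directory
#'
#' `session_write()` serializes a `tw_session` into a directory of
#' tab-separated arrays plus a JSON manifest (participant, trial table,
#' seeds, and the neural forward-map tensors so that oracle access to the
#' ground truth survives the round trip). `session_read()` restores it.
#'
#' @param session A `tw_session`.
#' @param dir Target directory (created if needed).
#' @param atlas Atlas used to revalidate the layout on read.
#' @return `dir` invisibly; the restored `tw_session` for `session_read`.
#' @export
session_write <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_layout(session$layout, file.path(dir, "layout.tsv"))
  readr::write_tsv(array_table(session$features, session$trials$trial_id),
                   file.path(dir, "features.tsv"))
  readr::write_tsv(array_table(session$specs, session$trials$trial_id),
                   file.path(dir, "specs.tsv"))
  readr::write_tsv(array_table(session$params, session$trials$trial_id),
                   file.path(dir, "params.tsv"))
  manifest <- list(
    participant_id = session$participant_id,
    frame_rate = session$frame_rate, n_bins = session$n_bins,
    fmax = session$fmax, seed = session$seed,
    trials = session$trials,
    split = session$trials$split,
    map = list(sources = as.vector(session$map$sources),
               weights = as.vector(session$map$weights),
               dim_weights = dim(session$map$weights),
               kernels = as.vector(session$map$kernels),
               sigma = session$map$sigma, seed = session$map$seed),
    true_mni = attr(session$layout, "true_mni"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname session_write
#' @export
session_read <- function(dir, atlas = load_atlas()) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  layout <- load_layout(file.path(dir, "layout.tsv"), atlas,
                        participant_id = man$participant_id)
  if (!is.null(man$true_mni)) {
    attr(layout, "true_mni") <- matrix(unlist(man$true_mni),
                                       ncol = 3, byrow = FALSE)
  }
  map <- structure(list(
    sources = array(man$map$sources, c(18, 2, 3)),
    weights = matrix(man$map$weights, man$map$dim_weights[1],
                     man$map$dim_weights[2]),
    kernels = matrix(man$map$kernels, 5, 18),
    sigma = man$map$sigma, seed = man$map$seed), class = "forward_map")
  trials <- tibble::as_tibble(man$trials)
  session <- structure(list(
    participant_id = man$participant_id, layout = layout, trials = trials,
    features = table_arrays(readr::read_tsv(
      file.path(dir, "features.tsv"), show_col_types = FALSE,
      col_types = readr::cols(.default = readr::col_character()))),
    specs = table_arrays(readr::read_tsv(
      file.path(dir, "specs.tsv"), show_col_types = FALSE,
      col_types = readr::cols(.default = readr::col_character()))),
    params = table_arrays(readr::read_tsv(
      file.path(dir, "params.tsv"), show_col_types = FALSE,
      col_types = readr::cols(.default = readr::col_character())),
      colnames_ = speech_param_names()),
    map = map, frame_rate = man$frame_rate, n_bins = man$n_bins,
    fmax = man$fmax, seed = man$seed), class = "tw_session")
  session
}
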