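#' @importFrom tibble tibble as_tibble
#' @importFrom rlang abort .data
NULL

#' Load a region-of-interest atlas
#'
#' An atlas names the cortical parcels used for the decoder's region
#' embeddings. It is data, not code: a tab-separated file with columns
#' `hemisphere` (`left`/`right`), `roi` (label) and `x`, `y`, `z` (a
#' representative MNI centroid in mm, used by the synthetic-participant
#' generator to assign regions by proximity). Left- and right-hemisphere
#' labels receive disjoint region indices so that separate embeddings are
#' learned per hemisphere; a reserved `Unknown` region (index 0) is shared and
#' holds electrodes whose location could not be determined.
#'
#' @param path Path to the atlas TSV. Defaults to the perisylvian atlas
#'   shipped with the package.
#' @return A `roi_atlas` object: a list with `regions` (tibble with
#'   `hemisphere`, `roi`, `roi_index`, `x`, `y`, `z`, including the Unknown
#'   row) and `n_regions` (total number of region indices, Unknown included).
#' @export
#' @examples
#' atlas <- load_atlas()
#' atlas$n_regions
load_atlas <- function(path = system.file("extdata", "atlas_default.tsv",
                                          package = "twspeech")) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    hemisphere = readr::col_character(),
    roi = readr::col_character(),
    x = readr::col_double(), y = readr::col_double(), z = readr::col_double()))
  if (!all(df$hemisphere %in% c("left", "right"))) {
    abort("atlas hemispheres must be 'left' or 'right'")
  }
  if ("Unknown" %in% df$roi) abort("'Unknown' is a reserved region label")
  df <- dplyr::arrange(df, match(.data$hemisphere, c("left", "right")))
  regions <- dplyr::bind_rows(
    tibble(hemisphere = "unknown", roi = "Unknown", roi_index = 0L,
           x = 0, y = 0, z = 0),
    dplyr::mutate(df, roi_index = seq_len(nrow(df)))
  )
  if (anyDuplicated(regions[, c("hemisphere", "roi")])) {
    abort("duplicated hemisphere/roi pair in atlas")
  }
  structure(list(regions = regions, n_regions = nrow(regions)),
            class = "roi_atlas")
}

#' @export
print.roi_atlas <- function(x, ...) {
  cat("<roi_atlas> ", x$n_regions, " region indices (incl. shared Unknown)\n",
      sep = "")
  print(dplyr::count(x$regions, .data$hemisphere))
  invisible(x)
}

atlas_index <- function(atlas, hemisphere, roi) {
  key <- paste(atlas$regions$hemisphere, atlas$regions$roi)
  idx <- match(paste(hemisphere, roi), key)
  atlas$regions$roi_index[idx]
}

#' Identify an atlas (and electrode table) with a short content hash
#' @noRd
content_hash <- function(x) {
  s <- paste(utils::capture.output(utils::str(x, digits.d = 15)), collapse = "\n")
  h <- 2166136261
  for (b in utf8ToInt(s)) h <- bitwAnd((bitwXor(h, b) * 16777619), 4294967295)
  sprintf("%08x", h)
}

ELECTRODE_KINDS <- c("grid", "strip", "depth", "sEEG", "unknown")

new_layout <- function(electrodes, atlas, participant_id = "p") {
  stopifnot(inherits(atlas, "roi_atlas"))
  electrodes <- as_tibble(electrodes)
  need <- c("id", "x", "y", "z", "roi", "hemisphere", "kind")
  if (!all(need %in% names(electrodes))) {
    abort(paste("layout needs columns:", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(electrodes$id)) {
    abort(paste("duplicate electrode id:",
                electrodes$id[duplicated(electrodes$id)][1]))
  }
  if (!all(electrodes$kind %in% ELECTRODE_KINDS)) {
    abort(paste("unknown electrode kind:",
                setdiff(electrodes$kind, ELECTRODE_KINDS)[1]))
  }
  # unknown-location electrodes: MNI fixed at the origin, region Unknown
  unk <- electrodes$x == 0 & electrodes$y == 0 & electrodes$z == 0
  electrodes$roi[unk] <- "Unknown"
  electrodes$hemisphere[unk] <- "unknown"
  electrodes$roi_index <- atlas_index(atlas, electrodes$hemisphere,
                                      electrodes$roi)
  if (anyNA(electrodes$roi_index)) {
    bad <- which(is.na(electrodes$roi_index))[1]
    abort(paste0("electrode '", electrodes$id[bad], "': region '",
                 electrodes$roi[bad], "' (", electrodes$hemisphere[bad],
                 ") not in atlas"))
  }
  structure(list(participant_id = participant_id,
                 electrodes = electrodes, atlas = atlas),
            class = "electrode_layout")
}

#' Load an electrode layout table
#'
#' Reads a tab-separated layout with header columns `id`, `x`, `y`, `z`
#' (MNI mm), `roi`, `hemisphere` (`left`/`right`/`unknown`) and `kind`
#' (`grid`/`strip`/`depth`/`sEEG`/`unknown`). Rows with empty coordinates
#' become unknown-location electrodes: their MNI coordinates are set to
#' (0, 0, 0) and their region to the reserved `Unknown` index; they are kept,
#' not discarded. The layout deliberately carries no 2D-grid index — electrode
#' identity is anatomical only.
#'
#' @param path Path to the layout TSV.
#' @param atlas A `roi_atlas` from [load_atlas()].
#' @param participant_id Participant label attached to the layout.
#' @return An `electrode_layout`: list with `participant_id`, `electrodes`
#'   (tibble, one row per electrode with its `roi_index`) and `atlas`.
#' @export
load_layout <- function(path, atlas = load_atlas(), participant_id = NULL) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  need <- c("id", "x", "y", "z", "roi", "hemisphere", "kind")
  if (!all(need %in% names(df))) {
    abort(paste("layout file must have columns:", paste(need, collapse = ", ")))
  }
  parse_coord <- function(v, axis) {
    v <- trimws(v)
    miss <- is.na(v) | v == ""
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!miss & is.na(out))
    if (length(bad)) {
      abort(paste0("unparseable ", axis, " coordinate '", v[bad[1]],
                   "' in layout row ", bad[1], " (id '", df$id[bad[1]], "')"))
    }
    list(value = out, missing = miss)
  }
  px <- parse_coord(df$x, "x"); py <- parse_coord(df$y, "y")
  pz <- parse_coord(df$z, "z")
  miss <- px$missing | py$missing | pz$missing
  df$x <- ifelse(miss, 0, px$value)
  df$y <- ifelse(miss, 0, py$value)
  df$z <- ifelse(miss, 0, pz$value)
  df$roi[miss] <- "Unknown"
  df$hemisphere[miss] <- "unknown"
  df$kind[is.na(df$kind) | df$kind == ""] <- "unknown"
  if (is.null(participant_id)) {
    participant_id <- sub("\\.[^.]*$", "", basename(path))
  }
  new_layout(df[, need], atlas, participant_id)
}

#' Write an electrode layout table
#'
#' Inverse of [load_layout()]: emits the same tab-separated dialect, so that
#' a load/write/load round trip reproduces every field exactly.
#'
#' @param layout An `electrode_layout`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  df <- layout$electrodes[, c("id", "x", "y", "z", "roi", "hemisphere", "kind")]
  for (a in c("x", "y", "z")) df[[a]] <- sprintf("%.17g", df[[a]])
  readr::write_tsv(df, path)
  invisible(path)
}

#' Hemisphere-qualified region index of an electrode
#'
#' Returns the index used for the decoder's region-embedding lookup. Left and
#' right hemispheres occupy disjoint index ranges (separate embedding
#' dictionaries); the shared `Unknown` region has index 0.
#'
#' @param layout An `electrode_layout`.
#' @param electrode_id Electrode id string.
#' @return A list with `hemisphere` and `roi_index`.
#' @export
roi_of <- function(layout, electrode_id) {
  i <- match(electrode_id, layout$electrodes$id)
  if (is.na(i)) abort(paste0("no electrode with id '", electrode_id, "'"))
  list(hemisphere = layout$electrodes$hemisphere[i],
       roi_index = layout$electrodes$roi_index[i])
}

#' @export
print.electrode_layout <- function(x, ...) {
  cat("<electrode_layout> participant '", x$participant_id, "', ",
      nrow(x$electrodes), " electrodes\n", sep = "")
  print(dplyr::count(x$electrodes, .data$kind, .data$hemisphere))
  invisible(x)
}

n_electrodes <- function(layout) nrow(layout$electrodes)

# MNI coordinate matrix (N x 3), raw mm
layout_mni <- function(layout) {
  as.matrix(layout$electrodes[, c("x", "y", "z")])
}

layout_hash <- function(layout) {
  content_hash(layout$electrodes[, c("id", "x", "y", "z", "roi",
                                     "hemisphere", "kind")])
}

# Deterministic canonical electrode order (by id). The decoder sorts
# electrodes internally with this permutation so that its output is exactly
# invariant to the order in which electrodes are listed.
layout_canonical_order <- function(layout) {
  order(layout$electrodes$id, method = "radix")
}

#' Reorder the electrodes of a layout
#'
#' Applies a permutation jointly usable on the columns of the paired neural
#' feature arrays. Mainly a testing/bookkeeping helper: decoding is invariant
#' to electrode order.
#'
#' @param layout An `electrode_layout`.
#' @param perm Integer permutation of `seq_len(n)`.
#' @return The permuted `electrode_layout`.
#' @export
permute_layout <- function(layout, perm) {
  stopifnot(identical(sort(perm), seq_len(nrow(layout$electrodes))))
  layout$electrodes <- layout$electrodes[perm, ]
  layout
}
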