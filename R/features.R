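#' Extract the per-sensor features of one recording
#'
#' Reduces one preprocessed (smoothed and trimmed) recording to its
#' 18-dimensional feature vector: per sensor, the maximum sample, the
#' arithmetic mean over the trimmed segment, and the stable value, defined as
#' the mean of the final `stable_frac` fraction of the segment (a robust
#' plateau estimate; the fraction is configurable).
#'
#' @param recording Rows of a preprocessed recordings tibble belonging to one
#'   recording (columns `time_s` plus the six sensor columns).
#' @param stable_frac Fraction of the segment tail used for the stable value
#'   (default 0.1).
#' @return A one-row tibble with 18 columns named per [feature_columns()].
#' @export
extract_features <- function(recording, stable_frac = 0.1) {
  sensors <- intersect(SENSOR_IDS, names(recording))
  if (length(sensors) != 6L) stop("recording must carry all six sensor columns", call. = FALSE)
  n <- nrow(recording)
  if (n == 0) stop("empty recording", call. = FALSE)
  n_stable <- max(1L, ceiling(stable_frac * n))
  vals <- lapply(sensors, function(s) {
    v <- recording[[s]]
    c(max(v), mean(v), mean(v[(n - n_stable + 1L):n]))
  })
  out <- as.list(unlist(vals))
  names(out) <- as.vector(t(outer(sensors, c("max", "avg", "stable"),
                                  paste, sep = "_")))
  tibble::as_tibble(out)[, feature_columns()]
}

#' Build the feature table of a dataset
#'
#' One row per recording, columns `recording_id`, `apple_id`, `grade` and the
#' 18 feature columns, ordered deterministically by `recording_id`. The
#' default 300-recording dataset yields a 300 x 18 feature table plus labels.
#'
#' @param recordings A preprocessed recordings tibble (see
#'   [preprocess_recordings()]); may be empty, in which case an empty table
#'   with the full schema is returned.
#' @param stable_frac Fraction of the segment tail used for the stable value
#'   (default 0.1).
#' @return A tibble of features with identifier and label columns.
#' @export
#' @examples
#' recs <- simulate_dataset(1, 2, seed = 1)
#' feats <- build_feature_table(preprocess_recordings(recs))
#' dim(feats)
build_feature_table <- function(recordings, stable_frac = 0.1) {
  schema <- c("recording_id", "apple_id", "grade", feature_columns())
  if (nrow(recordings) == 0) {
    empty <- tibble::as_tibble(setNames(
      c(list(character(), character(), character()),
        rep(list(numeric()), 18L)), schema))
    return(empty)
  }
  if (anyNA(recordings[, intersect(SENSOR_IDS, names(recordings))])) {
    stop("recordings contain missing values", call. = FALSE)
  }
  recordings <- dplyr::arrange(recordings, .data$recording_id, .data$time_s)
  ids <- unique(recordings[, c("recording_id", "apple_id", "grade")])
  if (anyDuplicated(ids$recording_id)) {
    stop("duplicate recording_id in input", call. = FALSE)
  }
  feats <- recordings |>
    dplyr::group_by(.data$recording_id, .data$apple_id, .data$grade) |>
    dplyr::group_modify(~ extract_features(.x, stable_frac = stable_frac)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$recording_id)
  feats[, schema]
}
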