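#' Write and read recordings as trace CSVs with a manifest
#'
#' Each recording is written to its own CSV with columns `time_s` and one
#' column per sensor (`MQ-9`, `MQ-3`, `MQ-6`, `MQ-8`, `MQ-2`, `MQ-135`),
#' header row mandatory, plus a `manifest.csv` with columns `recording_id`,
#' `apple_id`, `grade`, `path`. Output is byte-stable: rewriting the same
#' data produces identical files.
#'
#' @param recordings A recordings tibble (see [simulate_dataset()]).
#' @param dir Output directory (created if missing).
#' @return The manifest tibble, invisibly (`write_recordings`); the
#'   recordings tibble (`read_recordings`).
#' @export
write_recordings <- function(recordings, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sensors <- intersect(SENSOR_IDS, names(recordings))
  ids <- unique(recordings[, c("recording_id", "apple_id", "grade")])
  ids <- dplyr::arrange(ids, .data$recording_id)
  paths <- file.path(dir, paste0(ids$recording_id, ".csv"))
  for (i in seq_len(nrow(ids))) {
    rec <- recordings[recordings$recording_id == ids$recording_id[i],
                      c("time_s", sensors)]
    readr::write_csv(rec, paths[i])
  }
  manifest <- tibble::tibble(recording_id = ids$recording_id,
                             apple_id = ids$apple_id, grade = ids$grade,
                             path = basename(paths))
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' @rdname write_recordings
#' @param manifest Path to a manifest CSV; trace paths are resolved relative
#'   to its directory.
#' @export
read_recordings <- function(manifest) {
  man <- readr::read_csv(manifest, show_col_types = FALSE)
  base <- dirname(manifest)
  recs <- purrr::pmap_dfr(man, function(recording_id, apple_id, grade, path) {
    tr <- readr::read_csv(file.path(base, path), show_col_types = FALSE)
    dplyr::bind_cols(tibble::tibble(recording_id = recording_id,
                                    apple_id = apple_id, grade = grade), tr)
  })
  recs
}

#' Write and read feature tables
#'
#' Feature CSVs carry `recording_id`, `apple_id`, `grade` and the 18 feature
#' columns of [feature_columns()].
#'
#' @param features A feature table.
#' @param path CSV path.
#' @return The feature tibble (read) or `features` invisibly (write).
#' @export
write_features <- function(features, path) {
  readr::write_csv(features, path)
  invisible(features)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Serialize a KNN-SVM model to JSON
#'
#' The classifier is instance-based, so the training set is the model: the
#' JSON stores the training rows, labels, hyperparameters and a schema
#' version.
#'
#' @param model A [knn_svm()] model.
#' @param path JSON path.
#' @return The model (read) or `model` invisibly (write).
#' @export
write_knn_svm <- function(model, path) {
  obj <- list(schema_version = 1L,
              k = model$k, sigma = model$sigma, C = model$C,
              columns = model$columns,
              train_y = model$y,
              train_X = unname(apply(model$X, 1, as.numeric, simplify = FALSE)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(model)
}

#' @rdname write_knn_svm
#' @export
read_knn_svm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version) || obj$schema_version != 1L) {
    stop("unsupported model schema version", call. = FALSE)
  }
  X <- if (is.matrix(obj$train_X)) obj$train_X else
    do.call(rbind, lapply(obj$train_X, as.numeric))
  colnames(X) <- obj$columns
  structure(list(X = X, y = as.character(obj$train_y), k = as.integer(obj$k),
                 sigma = obj$sigma, C = obj$C, columns = obj$columns,
                 classes = sort(unique(as.character(obj$train_y)))),
            class = "knn_svm")
}
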