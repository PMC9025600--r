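#' Stratified (optionally apple-grouped) train/test split
#'
#' Splits a feature table into training and test partitions at the given
#' ratio, stratified by grade. By default all recordings of one apple stay
#' on the same side of the split (apples, not recordings, are the
#' independent units, so a row-level split would leak apple identity into
#' the test set); set `group_by_apple = FALSE` for a purely row-level split.
#' The default 300-row table splits 240/60.
#'
#' @param features A feature table from [build_feature_table()].
#' @param prop Training fraction (default 0.8, i.e. a 4:1 split).
#' @param group_by_apple Keep each apple's recordings together
#'   (default `TRUE`; requires an `apple_id` column).
#' @param seed Integer seed; the partition is deterministic given it.
#' @return A list of class `grading_split` with elements `train` and `test`.
#' @export
#' @examples
#' recs <- simulate_dataset(3, 2, seed = 1)
#' feats <- build_feature_table(preprocess_recordings(recs))
#' sp <- stratified_split(feats, seed = 1)
#' nrow(sp$train); nrow(sp$test)
stratified_split <- function(features, prop = 0.8, group_by_apple = TRUE,
                             seed = 1) {
  if (any(table(features$grade) < 2)) {
    stop("every grade needs at least 2 rows to split", call. = FALSE)
  }
  train_idx <- withr::with_seed(seed, {
    if (group_by_apple) {
      if (!"apple_id" %in% names(features)) {
        stop("group_by_apple = TRUE requires an apple_id column", call. = FALSE)
      }
      keep <- character()
      for (g in sort(unique(features$grade))) {
        apples <- sort(unique(features$apple_id[features$grade == g]))
        n_tr <- round(prop * length(apples))
        if (n_tr == 0 || n_tr == length(apples)) {
          stop("too few apples in grade ", g, " to split at ratio ", prop,
               call. = FALSE)
        }
        keep <- c(keep, sample(apples, n_tr))
      }
      which(features$apple_id %in% keep)
    } else {
      idx <- integer()
      for (g in sort(unique(features$grade))) {
        rows <- which(features$grade == g)
        n_tr <- round(prop * length(rows))
        idx <- c(idx, sample(rows, n_tr))
      }
      sort(idx)
    }
  })
  structure(list(train = features[train_idx, ],
                 test = features[-train_idx, ]),
            class = "grading_split")
}

#' @export
print.grading_split <- function(x, ...) {
  cat("grading split:", nrow(x$train), "train /", nrow(x$test), "test rows\n")
  invisible(x)
}

#' Evaluate a classifier on a train/test split
#'
#' Runs the full protocol for one feature space: the reducer (none, PCA or
#' LDA) is fitted on the training partition only and applied to both sides;
#' the classifier is trained on the (reduced) training rows, with KNN-SVM
#' hyperparameters selected by cross-validation inside the training set; and
#' recognition rates are measured on the test partition. The average
#' recognition rate is the mean of the per-class rates; the overall
#' test accuracy is also reported.
#'
#' @param train,test Disjoint feature tables sharing the feature schema.
#' @param reducer One of `"none"`, `"pca"`, `"lda"`.
#' @param classifier `"knn_svm"` (default), one of the baselines `"knn"`,
#'   `"svm"`, `"tree"`, `"rf"`, or a function
#'   `function(train, test, label_col)` returning predicted labels for
#'   `test` (useful for test doubles).
#' @param n_components Components retained by the reducer (default 2).
#' @param seed Seed for cross-validation folds and any stochastic
#'   classifier internals.
#' @param tune_args Optional list of arguments forwarded to
#'   [tune_knn_svm()] (e.g. smaller grids).
#' @param label_col Label column name (default `"grade"`).
#' @return An object of class `grading_eval` with per-class rates, the
#'   average and overall rates, the confusion matrix, the fitted reducer and
#'   classifier, and the training time in seconds (informational only).
#' @export
evaluate_grading <- function(train, test, reducer = c("none", "pca", "lda"),
                             classifier = "knn_svm", n_components = 2,
                             seed = 1, tune_args = list(),
                             label_col = "grade") {
  reducer <- match.arg(reducer)
  if ("recording_id" %in% names(train) && "recording_id" %in% names(test) &&
      length(intersect(train$recording_id, test$recording_id)) > 0) {
    stop("train and test must be disjoint", call. = FALSE)
  }
  red_model <- NULL
  if (reducer == "pca") {
    red_model <- fit_pca(train, n_components = n_components)
    train_r <- attach_label(predict(red_model, train), train, label_col)
    test_r <- attach_label(predict(red_model, test), test, label_col)
  } else if (reducer == "lda") {
    red_model <- fit_lda(train, label_col = label_col,
                         n_components = n_components)
    train_r <- attach_label(predict(red_model, train), train, label_col)
    test_r <- attach_label(predict(red_model, test), test, label_col)
  } else {
    train_r <- train
    test_r <- test
  }
  t0 <- proc.time()[["elapsed"]]
  preds <- fit_and_predict(classifier, train_r, test_r, seed, tune_args,
                           label_col)
  train_time <- proc.time()[["elapsed"]] - t0
  truth <- as.character(test_r[[label_col]])
  classes <- sort(unique(c(truth, as.character(train_r[[label_col]]))))
  confusion <- table(factor(truth, classes), factor(preds$labels, classes))
  per_class <- diag(confusion) / rowSums(confusion)
  report <- structure(
    list(classifier = preds$name, feature_space = reducer,
         per_class_rate = 100 * per_class,
         average_rate = 100 * mean(per_class, na.rm = TRUE),
         overall_rate = 100 * mean(preds$labels == truth),
         confusion = unclass(confusion),
         n_train = nrow(train), n_test = nrow(test),
         training_time_s = train_time,
         reducer_model = red_model, classifier_model = preds$model),
    class = "grading_eval"
  )
  report
}

attach_label <- function(scores, original, label_col) {
  if (!label_col %in% names(scores)) scores[[label_col]] <- original[[label_col]]
  scores
}

# Dispatch table for the classifiers of the comparison harness. Baselines
# are off-the-shelf implementations; only KNN-SVM is the package's own.
fit_and_predict <- function(classifier, train, test, seed, tune_args,
                            label_col) {
  if (is.function(classifier)) {
    return(list(labels = classifier(train, test, label_col),
                name = "custom", model = NULL))
  }
  num_cols <- setdiff(names(train)[vapply(train, is.numeric, logical(1))],
                      c(label_col, "recording_id", "apple_id"))
  Xtr <- as.matrix(train[, num_cols, drop = FALSE])
  Xte <- as.matrix(test[, num_cols, drop = FALSE])
  ytr <- factor(as.character(train[[label_col]]))
  switch(classifier,
    knn_svm = {
      tuned <- do.call(tune_knn_svm,
                       c(list(data = train, seed = seed,
                              label_col = label_col), tune_args))
      list(labels = predict(tuned$model, test), name = "knn_svm",
           model = tuned)
    },
    knn = {
      require_pkg("class")
      ks <- c(3, 5, 7, 9, 11)
      ks <- ks[ks < nrow(Xtr)]
      cv_acc <- withr::with_seed(seed, vapply(ks, function(k) {
        mean(class::knn.cv(Xtr, ytr, k = k) == ytr)
      }, numeric(1)))
      best_k <- ks[which.max(cv_acc)]
      labels <- withr::with_seed(seed,
        as.character(class::knn(Xtr, Xte, ytr, k = best_k)))
      list(labels = labels, name = "knn", model = list(k = best_k))
    },
    svm = {
      require_pkg("e1071")
      med <- median_pairwise_distance(Xtr)
      grid <- expand.grid(gamma = c(0.1, 1, 10) / med^2,
                          cost = c(0.1, 1, 10, 100))
      fold_id <- make_folds(as.character(ytr), 5, seed)
      acc <- vapply(seq_len(nrow(grid)), function(g) {
        correct <- 0L
        for (f in seq_len(5)) {
          fit <- e1071::svm(Xtr[fold_id != f, , drop = FALSE],
                            ytr[fold_id != f], kernel = "radial",
                            gamma = grid$gamma[g], cost = grid$cost[g])
          correct <- correct + sum(predict(fit, Xtr[fold_id == f, , drop = FALSE]) ==
                                     ytr[fold_id == f])
        }
        correct / length(ytr)
      }, numeric(1))
      best <- grid[which.max(acc), ]
      fit <- e1071::svm(Xtr, ytr, kernel = "radial", gamma = best$gamma,
                        cost = best$cost)
      list(labels = as.character(predict(fit, Xte)), name = "svm", model = fit)
    },
    tree = {
      require_pkg("rpart")
      df_tr <- data.frame(Xtr); df_tr$.y <- ytr
      df_te <- data.frame(Xte)
      fit <- rpart::rpart(.y ~ ., data = df_tr, method = "class")
      list(labels = as.character(predict(fit, df_te, type = "class")),
           name = "tree", model = fit)
    },
    rf = {
      require_pkg("randomForest")
      fit <- withr::with_seed(seed,
        randomForest::randomForest(Xtr, ytr, ntree = 300))
      list(labels = as.character(predict(fit, Xte)), name = "rf", model = fit)
    },
    stop("unknown classifier: ", classifier, call. = FALSE)
  )
}

require_pkg <- function(pkg) {
  if (!requireNamespace(pkg, quietly = TRUE)) {
    stop("package '", pkg, "' is required for this baseline", call. = FALSE)
  }
}

#' @export
print.grading_eval <- function(x, ...) {
  cat(sprintf("%s on %s features: average recognition rate %.2f%% (overall %.2f%%)\n",
              x$classifier, x$feature_space, x$average_rate, x$overall_rate))
  print(round(x$per_class_rate, 2))
  invisible(x)
}

#' @method tidy grading_eval
#' @export
tidy.grading_eval <- function(x, ...) {
  tibble::tibble(grade = names(x$per_class_rate),
                 recognition_rate = as.numeric(x$per_class_rate),
                 n_test = unname(rowSums(x$confusion)))
}

#' @method glance grading_eval
#' @export
glance.grading_eval <- function(x, ...) {
  tibble::tibble(classifier = x$classifier, feature_space = x$feature_space,
                 average_rate = x$average_rate, overall_rate = x$overall_rate,
                 n_train = x$n_train, n_test = x$n_test,
                 training_time_s = x$training_time_s)
}

#' Confusion-matrix heat map of an evaluation
#'
#' @param object A `grading_eval` report.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot grading_eval
#' @export
autoplot.grading_eval <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("truth", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::theme_minimal()
}

#' Compare KNN-SVM with four baseline classifiers
#'
#' Runs KNN-SVM plus KNN, SVM, Decision Tree and Random Forest on the same
#' split. Each classifier is evaluated in every requested feature space and
#' its best average recognition rate is reported as its final result. A
#' classifier that errors (e.g. on a degenerate single-class training set)
#' gets its error message recorded in its row rather than aborting the
#' table.
#'
#' @param train,test Disjoint feature tables.
#' @param reducers Feature spaces to try (default `c("none", "pca", "lda")`).
#' @param seed Seed forwarded to every classifier.
#' @param tune_args Arguments forwarded to [tune_knn_svm()] for the KNN-SVM
#'   rows.
#' @return A tibble with one row per classifier: `classifier`,
#'   `best_feature_space`, `average_rate`, `training_time_s`, `error`.
#' @export
compare_classifiers <- function(train, test,
                                reducers = c("none", "pca", "lda"),
                                seed = 1, tune_args = list()) {
  classifiers <- c("knn_svm", "knn", "svm", "tree", "rf")
  rows <- purrr::map_dfr(classifiers, function(cl) {
    res <- tryCatch({
      evals <- lapply(reducers, function(r) {
        evaluate_grading(train, test, reducer = r, classifier = cl,
                         seed = seed, tune_args = tune_args)
      })
      rates <- vapply(evals, function(e) e$average_rate, numeric(1))
      best <- evals[[which.max(rates)]]
      tibble::tibble(classifier = cl,
                     best_feature_space = best$feature_space,
                     average_rate = best$average_rate,
                     training_time_s = best$training_time_s,
                     error = NA_character_)
    }, error = function(e) {
      tibble::tibble(classifier = cl, best_feature_space = NA_character_,
                     average_rate = NA_real_, training_time_s = NA_real_,
                     error = conditionMessage(e))
    })
    res
  })
  rows
}

#' Run the full grading pipeline once
#'
#' Simulates a dataset, preprocesses it, extracts features, splits 4:1 with
#' apple grouping, and evaluates the chosen feature space with a
#' cross-validation-tuned KNN-SVM — the complete protocol in one call,
#' seeded end to end.
#'
#' @param seed Integer seed controlling simulation, split and folds.
#' @param reducer Feature space: `"none"`, `"pca"` or `"lda"`.
#' @param n_apples_per_grade,recordings_per_apple Dataset size
#'   (defaults 10 and 10: the 300-recording design).
#' @param profiles,config Generator settings (see [simulate_dataset()]).
#' @param window_len,poly_order,cutoff_s Preprocessing settings.
#' @param tune_args Arguments forwarded to [tune_knn_svm()].
#' @return A `grading_eval` report.
#' @export
run_grading_pipeline <- function(seed = 1, reducer = "lda",
                                 n_apples_per_grade = 10,
                                 recordings_per_apple = 10,
                                 profiles = default_sensor_profiles(),
                                 config = recording_config(),
                                 window_len = 21, poly_order = 3,
                                 cutoff_s = 20, tune_args = list()) {
  recs <- simulate_dataset(n_apples_per_grade, recordings_per_apple,
                           profiles = profiles, config = config, seed = seed)
  feats <- build_feature_table(
    preprocess_recordings(recs, window_len, poly_order, cutoff_s))
  sp <- stratified_split(feats, seed = seed)
  evaluate_grading(sp$train, sp$test, reducer = reducer, seed = seed,
                   tune_args = tune_args)
}
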