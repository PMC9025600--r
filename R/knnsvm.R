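#' Euclidean distance between two vectors
#'
#' \eqn{L(x_i, x_j) = (\sum_l |x_i(l) - x_j(l)|^2)^{1/2}}, the metric used
#' for neighbor search throughout the classifier.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Non-negative scalar distance.
#' @export
#' @examples
#' euclidean_distance(c(0, 0), c(3, 4))  # 5
euclidean_distance <- function(x, y) {
  if (length(x) != length(y)) stop("dimension mismatch", call. = FALSE)
  sqrt(sum((x - y)^2))
}

# All pairwise squared distances between the rows of A (n x d) and B (m x d).
cross_dist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

#' Gaussian radial kernel
#'
#' \eqn{k(x, x_i) = \exp(-\|x - x_i\|^2 / \sigma^2)} with the squared width
#' \eqn{\sigma^2} in the denominator. Values lie in \eqn{(0, 1]} with
#' \eqn{k(x, x) = 1}.
#'
#' @param x,y Numeric vectors of equal length.
#' @param sigma Kernel width, strictly positive.
#' @return Scalar similarity in `(0, 1]`.
#' @export
#' @examples
#' rbf_kernel(c(0, 0), c(1, 0), sigma = 1)  # exp(-1)
rbf_kernel <- function(x, y, sigma) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (length(x) != length(y)) stop("dimension mismatch", call. = FALSE)
  exp(-sum((x - y)^2) / sigma^2)
}

# Kernel Gram matrix between row sets from precomputed squared distances.
rbf_gram <- function(D2, sigma) exp(-D2 / sigma^2)

#' Fit a binary soft-margin SVM in the dual
#'
#' Solves the Gaussian-kernel soft-margin SVM dual
#' \deqn{\max_\alpha \sum_i \alpha_i - \tfrac12 \sum_{ij} \alpha_i \alpha_j
#'       y_i y_j k(x_i, x_j), \quad 0 \le \alpha_i \le C, \;
#'       \sum_i y_i \alpha_i = 0}
#' by sequential minimal optimization (maximal-violating-pair working-set
#' selection), giving the decision function
#' \eqn{f(x) = \sum_i \alpha_i y_i k(x, x_i) + b}.
#'
#' @param X Numeric matrix of training rows.
#' @param y Labels in `{-1, +1}` (numeric), one per row; both signs must be
#'   present.
#' @param sigma Gaussian kernel width.
#' @param C Box constraint (error penalty).
#' @param tol Stopping tolerance on the KKT violation (default 1e-8).
#' @return A list of class `svm_binary` with `alpha`, `b`, `objective`,
#'   `kkt_violation`, plus the training rows, labels and kernel parameters
#'   needed for prediction.
#' @export
svm_fit_binary <- function(X, y, sigma, C, tol = 1e-8) {
  X <- as.matrix(X)
  if (length(unique(sign(y))) < 2) stop("both classes must be present", call. = FALSE)
  if (sigma <= 0 || C <= 0) stop("sigma and C must be > 0", call. = FALSE)
  K <- rbf_gram(cross_dist2(X, X), sigma)
  fit <- smo_solve(K, as.numeric(y), C, tol = tol)
  structure(
    list(alpha = fit$alpha, b = fit$b, objective = fit$objective,
         kkt_violation = fit$kkt_violation, iterations = fit$iterations,
         X = X, y = as.numeric(y), sigma = sigma, C = C),
    class = "svm_binary"
  )
}

#' Decision values of a binary SVM
#'
#' @param object A fitted [svm_fit_binary()] model.
#' @param newdata Matrix of query rows.
#' @param ... Unused.
#' @return Numeric decision values \eqn{f(x)}; `sign(f)` is the predicted
#'   binary label.
#' @export
predict.svm_binary <- function(object, newdata, ...) {
  newdata <- matrix(as.numeric(newdata), ncol = ncol(object$X))
  K <- rbf_gram(cross_dist2(newdata, object$X), object$sigma)
  drop(K %*% (object$alpha * object$y) + object$b)
}

#' Train one-vs-rest local SVMs on a neighborhood
#'
#' For each class present among the rows, fits a binary soft-margin SVM of
#' that class against the rest (one-to-many multiclass scheme). Requires at
#' least two classes; a single-class neighborhood is handled upstream by the
#' unanimity shortcut of the hybrid classifier.
#'
#' @param X Numeric matrix of neighborhood rows.
#' @param y Character labels, one per row, at least two distinct values.
#' @param sigma,C Kernel width and error penalty shared by all binary
#'   problems.
#' @return A list of class `local_svm`: one [svm_fit_binary()] fit per class,
#'   in sorted class order.
#' @export
train_local_svm <- function(X, y, sigma, C) {
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2) {
    stop("neighborhood has a single class; use the unanimity shortcut", call. = FALSE)
  }
  fits <- lapply(classes, function(cl) {
    svm_fit_binary(X, ifelse(y == cl, 1, -1), sigma, C)
  })
  structure(list(fits = setNames(fits, classes), classes = classes),
            class = "local_svm")
}

#' Decision values of a one-vs-rest local SVM
#'
#' @param object A [train_local_svm()] fit.
#' @param newdata Matrix of query rows.
#' @param ... Unused.
#' @return Matrix of decision values, one column per class.
#' @export
predict.local_svm <- function(object, newdata, ...) {
  vals <- vapply(object$fits, function(f) predict(f, newdata),
                 numeric(NROW(newdata)))
  matrix(vals, ncol = length(object$classes),
         dimnames = list(NULL, object$classes))
}

#' Hybrid KNN-SVM classifier
#'
#' Instance-based hybrid classifier: for each query, the `k` nearest
#' training rows under Euclidean distance are found; if they all share one
#' label the query takes that label directly (unanimity shortcut, no SVM is
#' trained); otherwise a one-vs-rest Gaussian-kernel soft-margin SVM is
#' trained on just those `k` neighbors and the query takes the class with
#' the largest decision value. If every decision value is negative, the
#' nearest neighbor's label is used. With `k = 1` the classifier reduces
#' exactly to 1-nearest-neighbor; with `k` equal to the training size it
#' reduces to a global one-vs-rest SVM on mixed-label training sets.
#'
#' The model stores the training rows themselves (the training set is the
#' model); it operates in whatever feature space it is handed, raw 18-D
#' features or 2-D reduced scores alike.
#'
#' @param data A data frame holding the label column and numeric feature
#'   columns (all numeric columns other than the label are used).
#' @param k Neighbor count, `1 <= k <= nrow(data)`.
#' @param sigma Gaussian kernel width; default is the median pairwise
#'   training distance.
#' @param C Error penalty (default 1).
#' @param label_col Name of the label column (default `"grade"`).
#' @return An object of class `knn_svm`.
#' @export
#' @examples
#' set.seed(1)
#' d <- data.frame(grade = rep(c("L1", "L3"), each = 10),
#'                 x = c(rnorm(10), rnorm(10, 3)),
#'                 y = c(rnorm(10), rnorm(10, 3)))
#' fit <- knn_svm(d, k = 5)
#' predict(fit, d[1:3, ])
knn_svm <- function(data, k = 5, sigma = NULL, C = 1, label_col = "grade") {
  if (!label_col %in% names(data)) {
    stop("label column '", label_col, "' not found", call. = FALSE)
  }
  y <- as.character(data[[label_col]])
  num_cols <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                      label_col)
  num_cols <- setdiff(num_cols, c("recording_id", "apple_id"))
  X <- as.matrix(data[, num_cols, drop = FALSE])
  if (k < 1 || k > nrow(X)) stop("k must be between 1 and the training size", call. = FALSE)
  if (is.null(sigma)) sigma <- median_pairwise_distance(X)
  if (sigma <= 0 || C <= 0) stop("sigma and C must be > 0", call. = FALSE)
  structure(
    list(X = X, y = y, k = as.integer(k), sigma = sigma, C = C,
         columns = num_cols, classes = sort(unique(y))),
    class = "knn_svm"
  )
}

#' Median pairwise Euclidean distance
#'
#' The default scale for the Gaussian kernel width and the unit of the
#' kernel-width tuning grid.
#'
#' @param X Numeric matrix of rows.
#' @return Scalar median of all pairwise distances.
#' @export
median_pairwise_distance <- function(X) {
  median(stats::dist(X))
}

#' K nearest training rows of a query
#'
#' Indices of the `k` training rows nearest to `x` by Euclidean distance,
#' ordered by increasing distance with ties broken by ascending training
#' index (stable, deterministic).
#'
#' @param model A [knn_svm()] model.
#' @param x Numeric query vector in the model's feature space.
#' @param k Neighbor count (default: the model's `k`).
#' @return Integer vector of `k` training row indices.
#' @export
knn_query <- function(model, x, k = model$k) {
  if (length(x) != ncol(model$X)) stop("dimension mismatch", call. = FALSE)
  if (k > nrow(model$X)) stop("k exceeds the training size", call. = FALSE)
  d <- sqrt(colSums((t(model$X) - as.numeric(x))^2))
  order(d, seq_along(d))[seq_len(k)]
}

#' Predict grades with the hybrid KNN-SVM classifier
#'
#' @param object A [knn_svm()] model.
#' @param newdata Data frame or matrix of query rows in the model's feature
#'   space.
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.knn_svm <- function(object, newdata, ...) {
  Xq <- if (is.matrix(newdata)) newdata else matrix_by_columns(newdata, object$columns)
  D2 <- cross_dist2(Xq, object$X)
  ORD <- t(apply(D2, 1, function(d) order(d, seq_along(d))))
  knnsvm_predict_core(object$X, object$y, Xq, object$k, object$sigma,
                      object$C, ORD)
}

# Shared prediction core: neighbor order precomputed so tuning can reuse it
# across hyperparameter combinations.
knnsvm_predict_core <- function(Xtr, ytr, Xq, k, sigma, C, ORD) {
  n_q <- nrow(Xq)
  preds <- character(n_q)
  for (q in seq_len(n_q)) {
    nb <- ORD[q, seq_len(k)]
    lb <- ytr[nb]
    if (length(unique(lb)) == 1L) {
      preds[q] <- lb[1]  # unanimity shortcut: no SVM is trained
    } else {
      svm <- train_local_svm(Xtr[nb, , drop = FALSE], lb, sigma, C)
      vals <- predict(svm, Xq[q, , drop = FALSE])
      if (all(vals < 0)) {
        preds[q] <- lb[1]  # all classes reject: fall back to the nearest neighbor
      } else {
        preds[q] <- colnames(vals)[which.max(vals)]
      }
    }
  }
  preds
}

#' @export
print.knn_svm <- function(x, ...) {
  cat("KNN-SVM model:", nrow(x$X), "training rows in", ncol(x$X),
      "dimensions; k =", x$k, ", sigma =", signif(x$sigma, 4),
      ", C =", x$C, "\n")
  invisible(x)
}

#' @method glance knn_svm
#' @export
glance.knn_svm <- function(x, ...) {
  tibble::tibble(n_train = nrow(x$X), n_features = ncol(x$X),
                 n_classes = length(x$classes),
                 k = x$k, sigma = x$sigma, C = x$C)
}

# Stratified fold assignment: within each class, fold ids 1..folds are
# recycled and shuffled. Deterministic given the seed.
make_folds <- function(y, folds, seed) {
  if (folds < 2) stop("folds must be >= 2", call. = FALSE)
  if (any(table(y) < folds)) stop("every class needs at least `folds` members", call. = FALSE)
  fold_id <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in sort(unique(y))) {
      idx <- which(y == cl)
      fold_id[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
    }
  })
  fold_id
}

#' Cross-validated hyperparameter selection for KNN-SVM
#'
#' Grid search over the neighbor count `k`, the kernel width `sigma` and the
#' error penalty `C` by stratified cross-validation: the mean held-out
#' recognition rate is computed for every combination and the maximizer is
#' returned, with ties broken by smaller `k`, then smaller `C`, then smaller
#' `sigma`. Kernel widths are specified as multiples of the median pairwise
#' training distance, so the grid adapts to the feature space's scale.
#'
#' @param data Data frame with the label column and feature columns.
#' @param k_grid Neighbor counts (default `c(3, 5, 7, 9, 11)`).
#' @param sigma_mult Kernel width multipliers of the median pairwise
#'   distance (default `c(0.1, 0.3, 1, 3, 10)`).
#' @param C_grid Error penalties (default `c(0.1, 1, 10, 100)`).
#' @param folds Number of stratified folds (default 5).
#' @param seed Integer seed fixing the fold assignment.
#' @param label_col Name of the label column (default `"grade"`).
#' @return A list of class `knn_svm_tune`: `best` (a one-row tibble with
#'   `k`, `sigma`, `C`, `score`), `scores` (the full grid with CV scores)
#'   and `model` (a [knn_svm()] fitted on all of `data` at the selected
#'   hyperparameters).
#' @export
tune_knn_svm <- function(data, k_grid = c(3, 5, 7, 9, 11),
                         sigma_mult = c(0.1, 0.3, 1, 3, 10),
                         C_grid = c(0.1, 1, 10, 100),
                         folds = 5, seed = 1, label_col = "grade") {
  if (length(k_grid) == 0 || length(sigma_mult) == 0 || length(C_grid) == 0) {
    stop("hyperparameter grids must be non-empty", call. = FALSE)
  }
  y <- as.character(data[[label_col]])
  num_cols <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                      c(label_col, "recording_id", "apple_id"))
  X <- as.matrix(data[, num_cols, drop = FALSE])
  med <- median_pairwise_distance(X)
  sigma_grid <- sigma_mult * med
  fold_id <- make_folds(y, folds, seed)
  max_train <- nrow(X) - max(table(fold_id))
  k_grid <- k_grid[k_grid <= max_train]
  if (length(k_grid) == 0) stop("all k values exceed the fold training size", call. = FALSE)
  grid <- expand.grid(k = sort(k_grid), sigma = sort(sigma_grid),
                      C = sort(C_grid), KEEP.OUT.ATTRS = FALSE)
  hits <- matrix(0, nrow(grid), 2, dimnames = list(NULL, c("correct", "total")))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    Xte <- X[!tr, , drop = FALSE]; yte <- y[!tr]
    D2 <- cross_dist2(Xte, Xtr)
    ORD <- t(apply(D2, 1, function(d) order(d, seq_along(d))))
    for (g in seq_len(nrow(grid))) {
      p <- knnsvm_predict_core(Xtr, ytr, Xte, grid$k[g], grid$sigma[g],
                               grid$C[g], ORD)
      hits[g, ] <- hits[g, ] + c(sum(p == yte), length(yte))
    }
  }
  scores <- tibble::as_tibble(grid)
  scores$score <- hits[, "correct"] / hits[, "total"]
  # maximize score; ties -> smaller k, then smaller C, then smaller sigma
  ranked <- scores[order(-scores$score, scores$k, scores$C, scores$sigma), ]
  best <- ranked[1, ]
  model <- knn_svm(data, k = best$k, sigma = best$sigma, C = best$C,
                   label_col = label_col)
  structure(list(best = best, scores = scores, model = model,
                 median_distance = med, folds = folds, seed = seed),
            class = "knn_svm_tune")
}

#' @method tidy knn_svm_tune
#' @export
tidy.knn_svm_tune <- function(x, ...) x$scores

#' @method glance knn_svm_tune
#' @export
glance.knn_svm_tune <- function(x, ...) {
  dplyr::bind_cols(x$best, tibble::tibble(folds = x$folds,
                                          median_distance = x$median_distance))
}

#' @export
print.knn_svm_tune <- function(x, ...) {
  cat("KNN-SVM cross-validation over", nrow(x$scores), "combinations (",
      x$folds, "folds )\nselected:\n")
  print(x$best)
  invisible(x)
}
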