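#' Principal component analysis of a feature table
#'
#' Fits PCA from first principles on the feature columns: the population
#' mean \eqn{u = \frac{1}{m}\sum_j x_j}, the sample covariance
#' \eqn{S = \frac{1}{m-1}\sum_j (x_j - u)(x_j - u)^\top}, and the
#' eigendecomposition of \eqn{S}. Components are ordered by decreasing
#' eigenvalue; each component's contribution rate is its eigenvalue as a
#' fraction of the eigenvalue total. Features are centered but not
#' standardized (set `standardize = TRUE` to divide by per-column standard
#' deviations first).
#'
#' Eigenvectors are sign-ambiguous; for determinism each component is
#' flipped so that its largest-magnitude coordinate is positive.
#'
#' @param data A data frame containing the feature columns (identifier and
#'   label columns are ignored); alternatively any all-numeric data frame or
#'   matrix.
#' @param n_components Number of components retained by [predict()]
#'   (default 2). All components are stored, so full-rank reconstruction is
#'   possible.
#' @param standardize Divide each column by its standard deviation before
#'   fitting (default `FALSE`).
#' @return An object of class `enose_pca` with elements `mean`, `cov`,
#'   `rotation` (all components as columns), `eigenvalues`, `n_components`,
#'   `columns`.
#' @export
#' @examples
#' X <- data.frame(a = rnorm(50), b = rnorm(50))
#' fit <- fit_pca(X, n_components = 2)
#' glance(fit)
fit_pca <- function(data, n_components = 2, standardize = FALSE) {
  X <- reducer_input_matrix(data)
  m <- nrow(X)
  if (m < 2) stop("PCA needs at least 2 rows", call. = FALSE)
  if (n_components > ncol(X)) {
    stop("n_components exceeds the input dimension", call. = FALSE)
  }
  scale_sd <- if (standardize) apply(X, 2, sd) else rep(1, ncol(X))
  if (any(scale_sd == 0)) stop("cannot standardize a constant column", call. = FALSE)
  Xs <- sweep(X, 2, scale_sd, "/")
  u <- colMeans(Xs)
  Xc <- sweep(Xs, 2, u)
  S <- crossprod(Xc) / (m - 1)
  eig <- eigen(S, symmetric = TRUE)
  rotation <- fix_signs(eig$vectors)
  structure(
    list(mean = u, cov = S, rotation = rotation,
         eigenvalues = pmax(eig$values, 0), n_components = n_components,
         scale_sd = scale_sd, columns = colnames(X)),
    class = "enose_pca"
  )
}

#' Fisher linear discriminant analysis of a labeled feature table
#'
#' Fits LDA from first principles: per-class mean vectors \eqn{u_i}, the
#' between-class scatter \eqn{S_b = \sum_i (u_i - u)(u_i - u)^\top} (an
#' unweighted sum over class means), the within-class scatter
#' \eqn{S_w = \sum_i \sum_{k \in i} (x_k - u_i)(x_k - u_i)^\top}, and the
#' generalized eigenvectors of \eqn{S_w^{-1} S_b}, computed via a Cholesky
#' whitening of \eqn{S_w} so eigenvalues are real and non-negative. At most
#' \eqn{L - 1} eigenvalues are nonzero for \eqn{L} classes. If \eqn{S_w} is
#' singular a ridge \eqn{\epsilon I} with
#' \eqn{\epsilon = 10^{-8}\,\mathrm{tr}(S_w)/d} is added.
#'
#' @param data A data frame with the feature columns and a label column.
#' @param label_col Name of the label column (default `"grade"`).
#' @param n_components Number of discriminant directions retained by
#'   [predict()] (default 2, at most `L - 1` are informative).
#' @return An object of class `enose_lda` with elements `class_means`,
#'   `mean`, `Sb`, `Sw`, `rotation` (all directions as columns),
#'   `eigenvalues`, `n_components`, `columns`, `classes`.
#' @export
fit_lda <- function(data, label_col = "grade", n_components = 2) {
  if (!label_col %in% names(data)) {
    stop("label column '", label_col, "' not found", call. = FALSE)
  }
  y <- as.character(data[[label_col]])
  X <- reducer_input_matrix(data, drop_cols = label_col)
  classes <- sort(unique(y))
  L <- length(classes)
  if (L < 2) stop("LDA needs at least 2 classes", call. = FALSE)
  counts <- table(y)
  if (any(counts < 2)) stop("every class needs at least 2 rows", call. = FALSE)
  d <- ncol(X)
  u <- colMeans(X)
  class_means <- t(vapply(classes, function(cl) colMeans(X[y == cl, , drop = FALSE]),
                          numeric(d)))
  Sb <- matrix(0, d, d)
  Sw <- matrix(0, d, d)
  for (i in seq_len(L)) {
    diff <- class_means[i, ] - u
    Sb <- Sb + tcrossprod(diff)
    Xc <- sweep(X[y == classes[i], , drop = FALSE], 2, class_means[i, ])
    Sw <- Sw + crossprod(Xc)
  }
  if (sum(diag(Sw)) == 0) stop("all samples identical within classes: Sw is zero", call. = FALSE)
  ridge <- 1e-8 * sum(diag(Sw)) / d
  R <- tryCatch(chol(Sw), error = function(e) chol(Sw + ridge * diag(d)))
  # whiten: M = R^{-T} Sb R^{-1} is symmetric with the generalized eigenvalues
  M <- backsolve(R, t(backsolve(R, t(Sb), transpose = TRUE)), transpose = TRUE)
  M <- (M + t(M)) / 2
  eig <- eigen(M, symmetric = TRUE)
  directions <- backsolve(R, eig$vectors)
  directions <- sweep(directions, 2, sqrt(colSums(directions^2)), "/")
  directions <- fix_signs(directions)
  structure(
    list(class_means = class_means, mean = u, Sb = Sb, Sw = Sw,
         rotation = directions, eigenvalues = pmax(eig$values, 0),
         n_components = min(n_components, d), columns = colnames(X),
         classes = classes),
    class = "enose_lda"
  )
}

# Deterministic sign convention: flip each column so its largest-magnitude
# coordinate is positive.
fix_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

# Numeric input matrix for the reducers: keep the model feature schema if
# present, otherwise all numeric columns.
reducer_input_matrix <- function(data, drop_cols = character()) {
  if (is.matrix(data)) {
    if (is.null(colnames(data))) colnames(data) <- paste0("V", seq_len(ncol(data)))
    return(data)
  }
  if (all(feature_columns() %in% names(data))) {
    return(feature_matrix(data))
  }
  keep <- setdiff(names(data)[vapply(data, is.numeric, logical(1))], drop_cols)
  as.matrix(data[, keep, drop = FALSE])
}

#' Project data with a fitted reducer
#'
#' Centers `newdata` by the reducer's training mean and projects it onto the
#' stored directions; the reducer is never re-fitted, so held-out data are
#' transformed with training-set parameters only.
#'
#' @param object A fitted `enose_pca` or `enose_lda`.
#' @param newdata A data frame or matrix with the model's input columns.
#' @param n_components Number of components (default: the model's setting).
#' @param ... Unused.
#' @return A tibble of scores (`PC1..` or `LD1..`); identifier/label columns
#'   present in `newdata` (`recording_id`, `apple_id`, `grade`) are carried
#'   through.
#' @export
predict.enose_pca <- function(object, newdata, n_components = object$n_components, ...) {
  project_scores(object, newdata, n_components, prefix = "PC")
}

#' @rdname predict.enose_pca
#' @export
predict.enose_lda <- function(object, newdata, n_components = object$n_components, ...) {
  project_scores(object, newdata, n_components, prefix = "LD")
}

project_scores <- function(object, newdata, n_components, prefix) {
  X <- if (is.matrix(newdata)) newdata else matrix_by_columns(newdata, object$columns)
  if (ncol(X) != length(object$mean)) {
    stop("dimension mismatch: model expects ", length(object$mean), " columns",
         call. = FALSE)
  }
  if (!is.null(object$scale_sd)) X <- sweep(X, 2, object$scale_sd, "/")
  Xc <- sweep(X, 2, object$mean)
  scores <- Xc %*% object$rotation[, seq_len(n_components), drop = FALSE]
  colnames(scores) <- paste0(prefix, seq_len(n_components))
  out <- tibble::as_tibble(scores)
  if (is.data.frame(newdata)) {
    carry <- intersect(c("recording_id", "apple_id", "grade"), names(newdata))
    if (length(carry) > 0) out <- dplyr::bind_cols(newdata[, carry, drop = FALSE], out)
  }
  out
}

#' Reconstruct data from PCA scores
#'
#' Inverse projection: maps scores back to the original space using the
#' stored rotation and training mean. With all components retained this
#' reconstructs the input exactly (orthonormal completeness).
#'
#' @param object A fitted `enose_pca`.
#' @param scores A matrix or tibble of score columns (`PC1`, `PC2`, ...).
#' @return A matrix in the original feature space.
#' @export
pca_reconstruct <- function(object, scores) {
  S <- as.matrix(scores[, grep("^PC", colnames(scores)), drop = FALSE])
  k <- ncol(S)
  X <- S %*% t(object$rotation[, seq_len(k), drop = FALSE])
  X <- sweep(X, 2, object$mean, "+")
  if (!is.null(object$scale_sd)) X <- sweep(X, 2, object$scale_sd, "*")
  colnames(X) <- object$columns
  X
}

#' Component contribution table
#'
#' Per-component eigenvalue, variance contribution rate (percent of the
#' eigenvalue total) and cumulative contribution rate, in decreasing
#' eigenvalue order. Rates sum to 100 over all components.
#'
#' @param model A fitted `enose_pca` or `enose_lda`.
#' @param digits Rounding applied to the percentage columns (default 2).
#' @return A tibble with columns `component`, `eigenvalue`,
#'   `contribution_pct`, `cumulative_pct`.
#' @export
contribution_table <- function(model, digits = 2) {
  if (!inherits(model, c("enose_pca", "enose_lda"))) {
    stop("model must be a fitted enose_pca or enose_lda", call. = FALSE)
  }
  prefix <- if (inherits(model, "enose_pca")) "PC" else "LD"
  ev <- model$eigenvalues
  pct <- 100 * ev / sum(ev)
  tibble::tibble(
    component = paste0(prefix, seq_along(ev)),
    eigenvalue = ev,
    contribution_pct = round(pct, digits),
    cumulative_pct = round(cumsum(pct), digits)
  )
}

#' @method tidy enose_pca
#' @export
tidy.enose_pca <- function(x, ...) contribution_table(x, ...)

#' @method tidy enose_lda
#' @export
tidy.enose_lda <- function(x, ...) contribution_table(x, ...)

#' @method glance enose_pca
#' @export
glance.enose_pca <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$mean),
    n_components = x$n_components,
    total_variance = sum(x$eigenvalues),
    var_explained_retained = sum(x$eigenvalues[seq_len(x$n_components)]) /
      sum(x$eigenvalues)
  )
}

#' @method glance enose_lda
#' @export
glance.enose_lda <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$mean),
    n_classes = length(x$classes),
    n_components = x$n_components,
    contribution_retained = sum(x$eigenvalues[seq_len(x$n_components)]) /
      sum(x$eigenvalues)
  )
}

#' @export
print.enose_pca <- function(x, ...) {
  cat("PCA model:", length(x$mean), "features,", x$n_components,
      "retained components\n")
  print(head(contribution_table(x), 4))
  invisible(x)
}

#' @export
print.enose_lda <- function(x, ...) {
  cat("LDA model:", length(x$mean), "features,", length(x$classes),
      "classes,", x$n_components, "retained directions\n")
  print(head(contribution_table(x), 3))
  invisible(x)
}

#' Score scatter plot for a fitted reducer
#'
#' Projects `data` with the reducer and draws the first two score dimensions
#' colored by grade, the standard way of inspecting class separation after
#' dimensionality reduction.
#'
#' @param object A fitted `enose_pca` or `enose_lda`.
#' @param data A feature table with a `grade` column.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot enose_pca
#' @export
autoplot.enose_pca <- function(object, data, ...) {
  plot_reducer_scores(object, data, "PC")
}

#' @rdname autoplot.enose_pca
#' @method autoplot enose_lda
#' @export
autoplot.enose_lda <- function(object, data, ...) {
  plot_reducer_scores(object, data, "LD")
}

plot_reducer_scores <- function(object, data, prefix) {
  sc <- predict(object, data, n_components = 2)
  ggplot2::ggplot(sc, ggplot2::aes(.data[[paste0(prefix, 1)]],
                                   .data[[paste0(prefix, 2)]],
                                   colour = .data$grade)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(colour = "grade") +
    ggplot2::theme_minimal()
}
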