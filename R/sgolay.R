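#' Savitzky-Golay smoothing coefficients
#'
#' Computes the central-point Savitzky-Golay convolution weights from first
#' principles: a polynomial of degree `poly_order` is least-squares fitted to
#' each window of `window_len` samples and evaluated at the window center,
#' which is a linear operation on the window, i.e. a convolution. The weights
#' are the center row of the polynomial hat matrix
#' \eqn{A(A^\top A)^{-1}A^\top} for the local design matrix
#' \eqn{A_{ij} = t_i^{j}}, \eqn{t_i \in \{-h, \dots, h\}}.
#'
#' @param window_len Odd window length, at least 3.
#' @param poly_order Polynomial order, non-negative and less than
#'   `window_len`.
#' @return Numeric vector of `window_len` weights (they sum to 1).
#' @export
#' @examples
#' sg_coefficients(3, 0)  # order-0 SG filter is the moving average
sg_coefficients <- function(window_len, poly_order) {
  check_sg_params(window_len, poly_order)
  h <- (window_len - 1L) / 2L
  A <- outer(seq(-h, h), 0:poly_order, `^`)
  # center row of the hat matrix A (A'A)^{-1} A'
  hat_center <- A[h + 1L, , drop = FALSE] %*% solve(crossprod(A), t(A))
  drop(hat_center)
}

check_sg_params <- function(window_len, poly_order) {
  if (window_len < 3 || window_len %% 2 == 0) {
    stop("window_len must be an odd integer >= 3", call. = FALSE)
  }
  if (poly_order < 0 || poly_order >= window_len) {
    stop("poly_order must satisfy 0 <= poly_order < window_len", call. = FALSE)
  }
  invisible(TRUE)
}

# Hat matrix of a full local polynomial fit across one window; used to
# smooth the boundary samples by evaluating the first/last window's
# least-squares polynomial at the edge positions (preserves exact
# reproduction of polynomials up to poly_order over the whole trace).
# Centered positions keep the normal equations well conditioned.
sg_boundary_hat <- function(window_len, poly_order) {
  h <- (window_len - 1L) / 2L
  A <- outer(seq(-h, h), 0:poly_order, `^`)
  A %*% solve(crossprod(A), t(A))
}

#' Savitzky-Golay filter
#'
#' Smooths a signal with the Savitzky-Golay filter: interior samples are the
#' convolution with [sg_coefficients()]; the `(window_len - 1)/2` samples at
#' each end are smoothed by fitting the local polynomial to the first/last
#' full window and evaluating it at the edge positions, so a polynomial of
#' degree at most `poly_order` is reproduced exactly everywhere and the
#' output has the same length as the input.
#'
#' @param x Numeric vector (or matrix: columns are filtered independently).
#' @param window_len Odd window length, at least 3 (default 21).
#' @param poly_order Polynomial order (default 3).
#' @return Smoothed numeric vector (or matrix) of the same shape as `x`.
#' @export
#' @examples
#' x <- sin(seq(0, 2 * pi, length.out = 100)) + rnorm(100, 0, 0.05)
#' xs <- sg_filter(x, 11, 3)
sg_filter <- function(x, window_len = 21, poly_order = 3) {
  check_sg_params(window_len, poly_order)
  X <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  n <- nrow(X)
  if (n < window_len) {
    stop("signal shorter than the filter window", call. = FALSE)
  }
  w <- sg_coefficients(window_len, poly_order)
  h <- (window_len - 1L) / 2L
  out <- stats::filter(X, w, sides = 2)
  out <- matrix(as.numeric(out), nrow = n)
  # boundary samples via local polynomial fit on the first/last window
  H <- sg_boundary_hat(window_len, poly_order)
  first_fit <- H %*% X[seq_len(window_len), , drop = FALSE]
  last_fit <- H %*% X[(n - window_len + 1L):n, , drop = FALSE]
  out[seq_len(h), ] <- first_fit[seq_len(h), , drop = FALSE]
  out[(n - h + 1L):n, ] <- last_fit[(window_len - h + 1L):window_len, , drop = FALSE]
  if (is.matrix(x)) out else drop(out)
}

#' Trim the pre-steady-state transient
#'
#' Sensor responses stabilize only after an initial transient; samples before
#' `cutoff_s` are discarded and only samples with `time_s >= cutoff_s` are
#' kept, matching the convention of extracting features from the
#' post-transient curve.
#'
#' @param data A data frame with a `time_s` column (a single trace or a
#'   multi-recording tibble from [simulate_dataset()]).
#' @param cutoff_s Transient cutoff in seconds (default 20).
#' @return The rows of `data` with `time_s >= cutoff_s`.
#' @export
trim_transient <- function(data, cutoff_s = 20) {
  if (!"time_s" %in% names(data)) stop("data must have a time_s column", call. = FALSE)
  out <- dplyr::filter(data, .data$time_s >= cutoff_s)
  if (nrow(out) == 0) {
    stop("recording shorter than the transient cutoff: nothing remains after trimming",
         call. = FALSE)
  }
  out
}

#' Preprocess a recordings table
#'
#' Applies Savitzky-Golay smoothing to every sensor trace of every recording
#' (full trace, before trimming, so filter edge effects do not land at the
#' cutoff boundary) and then trims the pre-steady-state transient.
#'
#' @param recordings A recordings tibble from [simulate_dataset()] or
#'   [read_recordings()].
#' @param window_len,poly_order Savitzky-Golay parameters (defaults 21 and 3).
#' @param cutoff_s Transient cutoff in seconds (default 20).
#' @return A recordings tibble of the same shape with smoothed voltages and
#'   only post-cutoff samples.
#' @export
#' @examples
#' recs <- simulate_dataset(1, 1, seed = 1)
#' pre <- preprocess_recordings(recs)
#' range(pre$time_s)
preprocess_recordings <- function(recordings, window_len = 21, poly_order = 3,
                                  cutoff_s = 20) {
  sensors <- intersect(SENSOR_IDS, names(recordings))
  if (length(sensors) == 0) stop("no sensor columns found", call. = FALSE)
  recordings <- dplyr::arrange(recordings, .data$recording_id, .data$time_s)
  lens <- table(recordings$recording_id)
  if (length(unique(as.integer(lens))) != 1L) {
    stop("all recordings must share one time base", call. = FALSE)
  }
  n <- as.integer(lens[1])
  for (s in sensors) {
    m <- matrix(recordings[[s]], nrow = n)
    recordings[[s]] <- as.numeric(sg_filter(m, window_len, poly_order))
  }
  trim_transient(recordings, cutoff_s)
}
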