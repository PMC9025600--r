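# Independent oracles used across the suite. Each deliberately takes a
# different computational route from the production code it checks.

# Savitzky-Golay smoothing of one sample by an explicit per-window
# least-squares polynomial fit (lm on the window, predicted at the center).
sg_lsq_oracle_weights <- function(window_len, poly_order) {
  h <- (window_len - 1) / 2
  pos <- seq(-h, h)
  # weight on sample j = smoothed center value when the input is e_j
  vapply(seq_len(window_len), function(j) {
    y <- numeric(window_len); y[j] <- 1
    fit <- lm(y ~ poly(pos, degree = max(poly_order, 1), raw = TRUE))
    co <- coef(fit)
    if (poly_order == 0) mean(y) else unname(co[1])  # value at pos = 0
  }, numeric(1))
}

# Exact dual optimum of the soft-margin SVM by active-set enumeration: each
# alpha_i is at 0, at C, or free; free variables and the equality multiplier
# solve the stationarity system; the best box-and-equality-feasible
# candidate is the optimum (the true solution satisfies some assignment).
svm_dual_oracle <- function(K, y, C) {
  n <- length(y)
  Q <- outer(y, y) * K
  objective <- function(a) sum(a) - 0.5 * drop(t(a) %*% Q %*% a)
  best <- -Inf
  states <- expand.grid(rep(list(c("zero", "cap", "free")), n),
                        stringsAsFactors = FALSE)
  for (r in seq_len(nrow(states))) {
    st <- as.character(states[r, ])
    a <- numeric(n)
    a[st == "cap"] <- C
    free <- which(st == "free")
    if (length(free) > 0) {
      # [ Q_FF  y_F ] [a_F]   [ 1 - Q_FB a_B ]
      # [ y_F'  0   ] [ mu] = [ -y_B' a_B    ]
      bound <- setdiff(seq_len(n), free)
      rhs_top <- rep(1, length(free))
      if (length(bound)) {
        rhs_top <- rhs_top - drop(Q[free, bound, drop = FALSE] %*% a[bound])
      }
      rhs <- c(rhs_top, -sum(y[bound] * a[bound]))
      A <- rbind(cbind(Q[free, free, drop = FALSE], y[free]),
                 c(y[free], 0))
      sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      a[free] <- sol[seq_along(free)]
      if (any(a[free] < -1e-9) || any(a[free] > C + 1e-9)) next
      a[free] <- pmin(pmax(a[free], 0), C)
    }
    if (abs(sum(y * a)) > 1e-8 * max(1, C)) next
    obj <- objective(a)
    if (obj > best) best <- obj
  }
  best
}

# Random small SVM instance with both labels present.
random_svm_instance <- function(n, d = 2) {
  repeat {
    y <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(y)) == 2) break
  }
  list(X = matrix(rnorm(n * d), n, d), y = y)
}

# Small labeled 2-D Gaussian clusters for classifier tests.
make_clusters <- function(n_per = 15, sep = 4, sd = 1, labels = c("L1", "L2", "L3")) {
  centers <- rbind(c(0, 0), c(sep, 0), c(0, sep))[seq_along(labels), , drop = FALSE]
  X <- do.call(rbind, lapply(seq_along(labels), function(i) {
    cbind(rnorm(n_per, centers[i, 1], sd), rnorm(n_per, centers[i, 2], sd))
  }))
  data.frame(grade = rep(labels, each = n_per), x1 = X[, 1], x2 = X[, 2],
             stringsAsFactors = FALSE)
}

# Small simulated feature table shared by several tests (built once).
small_feature_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      recs <- simulate_dataset(5, 4, seed = 42)
      cache <<- build_feature_table(preprocess_recordings(recs))
    }
    cache
  }
})
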