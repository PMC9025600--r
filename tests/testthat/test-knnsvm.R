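test_that("knn_query returns neighbors by distance with stable ties", {
  d <- data.frame(grade = c("L1", "L1", "L2", "L2"),
                  x = c(0, 1, 2, 10))
  m <- knn_svm(d, k = 2, sigma = 1)
  expect_equal(knn_query(m, 0.4, k = 3), c(1L, 2L, 3L))
  # query equidistant from rows 2 and 3: ascending index breaks the tie
  expect_equal(knn_query(m, 1.5, k = 2), c(2L, 3L))
  expect_error(knn_query(m, c(0, 0)), "dimension")
  expect_error(knn_query(m, 0, k = 9), "exceeds")
})

test_that("knn_query agrees with a brute-force oracle", {
  set.seed(17)
  d <- make_clusters(n_per = 10)
  m <- knn_svm(d, k = 5)
  for (i in 1:10) {
    x <- rnorm(2, 1, 2)
    dists <- apply(as.matrix(d[, c("x1", "x2")]), 1,
                   function(r) euclidean_distance(r, x))
    expect_equal(knn_query(m, x, k = 4), order(dists)[1:4])
  }
})

test_that("k = 1 reduces exactly to the nearest-neighbor rule", {
  set.seed(23)
  d <- make_clusters(n_per = 12, sep = 2, sd = 1.5)
  m <- knn_svm(d, k = 1)
  queries <- make_clusters(n_per = 8, sep = 2, sd = 1.5)
  pred <- predict(m, queries)
  nn_oracle <- apply(cross_dist2(as.matrix(queries[, c("x1", "x2")]),
                                 as.matrix(d[, c("x1", "x2")])), 1, which.min)
  expect_equal(pred, d$grade[nn_oracle])
})

test_that("unanimous neighborhoods never train an SVM", {
  d <- data.frame(grade = rep(c("L1", "L2"), each = 5),
                  x = c(1:5, 101:105))
  X <- as.matrix(d$x)
  D2 <- cross_dist2(matrix(c(3, 103), 2, 1), X)
  ORD <- t(apply(D2, 1, function(dd) order(dd, seq_along(dd))))
  # sigma = NA would make any SVM fit error out, so a successful call
  # proves the shortcut path is taken
  pred <- knnsvm_predict_core(X, d$grade, matrix(c(3, 103), 2, 1),
                              k = 5, sigma = NA_real_, C = NA_real_, ORD = ORD)
  expect_equal(pred, c("L1", "L2"))
})

test_that("mixed neighborhoods go through the local SVM", {
  d <- data.frame(grade = rep(c("L1", "L2"), each = 5),
                  x = c(1:5, 6:10))
  m <- knn_svm(d, k = 4, sigma = 5, C = 10)
  # query at 5.4: neighbors {5, 6, 4, 7} are mixed
  expect_equal(predict(m, matrix(5.4)), "L1")
  expect_equal(predict(m, matrix(5.9)), "L2")
})

test_that("k = training size reduces to a global one-vs-rest SVM", {
  set.seed(29)
  d <- make_clusters(n_per = 7, sep = 3, sd = 1)
  n <- nrow(d)
  m <- knn_svm(d, k = n, sigma = 2, C = 5)
  queries <- as.matrix(make_clusters(n_per = 4, sep = 3, sd = 1)[, c("x1", "x2")])
  pred <- predict(m, queries)
  global <- train_local_svm(as.matrix(d[, c("x1", "x2")]), d$grade,
                            sigma = 2, C = 5)
  vals <- predict(global, queries)
  nn <- apply(cross_dist2(queries, as.matrix(d[, c("x1", "x2")])), 1, which.min)
  oracle <- ifelse(apply(vals, 1, max) < 0, d$grade[nn],
                   colnames(vals)[apply(vals, 1, which.max)])
  expect_equal(pred, oracle)
})

test_that("prediction is deterministic and invariant to training row order", {
  set.seed(37)
  d <- make_clusters(n_per = 10, sep = 4, sd = 0.8)
  q <- make_clusters(n_per = 5, sep = 4, sd = 0.8)
  m1 <- knn_svm(d, k = 5, sigma = 2, C = 10)
  m2 <- knn_svm(d[sample(nrow(d)), ], k = 5, sigma = 2, C = 10)
  expect_equal(predict(m1, q), predict(m1, q))
  expect_equal(predict(m1, q), predict(m2, q))
})

test_that("model construction validates inputs and defaults sigma", {
  d <- make_clusters(n_per = 5)
  expect_error(knn_svm(d, k = 0), "k must be")
  expect_error(knn_svm(d, k = 99), "k must be")
  expect_error(knn_svm(d, label_col = "nope"), "not found")
  expect_error(knn_svm(d, sigma = -1), "sigma")
  m <- knn_svm(d, k = 3)
  expect_equal(m$sigma, median_pairwise_distance(as.matrix(d[, c("x1", "x2")])))
  expect_equal(m$classes, c("L1", "L2", "L3"))
  expect_output(print(m), "KNN-SVM model")
  expect_equal(glance(m)$n_train, nrow(d))
})

test_that("stratified folds are balanced, deterministic and validated", {
  y <- rep(c("L1", "L2", "L3"), each = 20)
  f1 <- make_folds(y, 5, seed = 3)
  f2 <- make_folds(y, 5, seed = 3)
  expect_identical(f1, f2)
  expect_equal(sort(unique(f1)), 1:5)
  tab <- table(y, f1)
  expect_true(all(tab == 4))  # 20 per class over 5 folds
  expect_error(make_folds(y, 1, seed = 1), "folds")
  expect_error(make_folds(c("L1", "L2"), 3, seed = 1), "at least")
})

test_that("a single-combination grid is selected verbatim", {
  set.seed(41)
  d <- make_clusters(n_per = 10, sep = 4, sd = 0.8)
  tuned <- tune_knn_svm(d, k_grid = 5, sigma_mult = 1, C_grid = 10,
                        folds = 3, seed = 2)
  expect_equal(nrow(tuned$scores), 1)
  expect_equal(tuned$best$k, 5)
  expect_equal(tuned$best$C, 10)
  expect_equal(tuned$best$sigma, tuned$median_distance)
  expect_s3_class(tuned$model, "knn_svm")
  expect_equal(tidy(tuned), tuned$scores)
  expect_equal(glance(tuned)$folds, 3)
  expect_output(print(tuned), "cross-validation")
})

test_that("tuning picks the grid maximum and scores lie in [0, 1]", {
  set.seed(43)
  d <- make_clusters(n_per = 12, sep = 4, sd = 1)
  tuned <- tune_knn_svm(d, k_grid = c(3, 5), sigma_mult = c(0.3, 1),
                        C_grid = c(1, 10), folds = 3, seed = 7)
  expect_true(all(tuned$scores$score >= 0 & tuned$scores$score <= 1))
  expect_equal(tuned$best$score, max(tuned$scores$score))
  expect_gte(tuned$best$score, 0.9)  # well-separated clusters
  # tie-break: among the maximizers the smallest k, then C, then sigma wins
  top <- tuned$scores[tuned$scores$score == tuned$best$score, ]
  top <- top[order(top$k, top$C, top$sigma), ]
  expect_equal(tuned$best$k, top$k[1])
  expect_equal(tuned$best$C, top$C[1])
  expect_equal(tuned$best$sigma, top$sigma[1])
})

test_that("tuning is reproducible and filters infeasible k values", {
  set.seed(47)
  d <- make_clusters(n_per = 6, sep = 4, sd = 0.8)
  t1 <- tune_knn_svm(d, k_grid = c(3, 5), sigma_mult = 1, C_grid = 1,
                     folds = 3, seed = 11)
  t2 <- tune_knn_svm(d, k_grid = c(3, 5), sigma_mult = 1, C_grid = 1,
                     folds = 3, seed = 11)
  expect_identical(t1$best, t2$best)
  expect_error(tune_knn_svm(d, k_grid = 1000, sigma_mult = 1, C_grid = 1,
                            folds = 3, seed = 1), "exceed")
})

test_that("the tuned classifier grades the simulated feature table well", {
  tab <- small_feature_table()
  tuned <- tune_knn_svm(tab, k_grid = 5, sigma_mult = 1, C_grid = 1,
                        folds = 3, seed = 5)
  pred <- predict(tuned$model, tab)
  expect_gte(mean(pred == tab$grade), 0.9)  # resubstitution on separable data
})
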