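test_that("the default design splits 240/60 with stratified grades", {
  recs <- simulate_dataset(10, 10, seed = 1,
                           config = recording_config(duration_s = 40))
  feats <- build_feature_table(preprocess_recordings(recs))
  sp <- stratified_split(feats, seed = 1)
  expect_s3_class(sp, "grading_split")
  expect_equal(nrow(sp$train), 240)
  expect_equal(nrow(sp$test), 60)
  expect_equal(as.vector(table(sp$train$grade)), rep(80, 3))
  expect_equal(as.vector(table(sp$test$grade)), rep(20, 3))
  expect_length(intersect(sp$train$recording_id, sp$test$recording_id), 0)
  expect_output(print(sp), "240 train / 60 test")
})

test_that("apple grouping keeps every apple on one side of the split", {
  tab <- small_feature_table()
  sp <- stratified_split(tab, seed = 7)
  expect_length(intersect(sp$train$apple_id, sp$test$apple_id), 0)
  # 5 apples per grade at 0.8 -> 4 train + 1 test apple per grade
  expect_equal(as.vector(table(sp$test$grade)), rep(4, 3))
})

test_that("row-level stratified split honors the ratio per grade", {
  set.seed(1)
  d <- make_clusters(n_per = 100)
  sp <- stratified_split(d, prop = 0.8, group_by_apple = FALSE, seed = 2)
  expect_equal(as.vector(table(sp$train$grade)), rep(80, 3))
  expect_equal(as.vector(table(sp$test$grade)), rep(20, 3))
  expect_equal(nrow(sp$train) + nrow(sp$test), 300)
})

test_that("splits are deterministic in the seed and validate inputs", {
  tab <- small_feature_table()
  s1 <- stratified_split(tab, seed = 4)
  s2 <- stratified_split(tab, seed = 4)
  expect_identical(s1$train$recording_id, s2$train$recording_id)
  s3 <- stratified_split(tab, seed = 5)
  expect_false(identical(s1$train$recording_id, s3$train$recording_id))
  expect_error(stratified_split(dplyr::select(tab, -apple_id), seed = 1),
               "apple_id")
  expect_error(stratified_split(tab[c(1, 21), ], seed = 1), "at least 2 rows")
  expect_error(stratified_split(tab[1:4, ], seed = 1), "too few apples")
})

test_that("a perfect test double scores 100 and a constant one 33.33", {
  tab <- small_feature_table()
  sp <- stratified_split(tab, seed = 1)
  perfect <- function(train, test, label_col) as.character(test[[label_col]])
  ev <- evaluate_grading(sp$train, sp$test, reducer = "none",
                         classifier = perfect)
  expect_equal(ev$average_rate, 100)
  expect_equal(ev$overall_rate, 100)
  expect_equal(unname(ev$per_class_rate), rep(100, 3))
  constant <- function(train, test, label_col) rep("L1", nrow(test))
  ev2 <- evaluate_grading(sp$train, sp$test, reducer = "none",
                          classifier = constant)
  expect_equal(ev2$average_rate, 100 / 3, tolerance = 1e-10)
  expect_equal(unname(ev2$per_class_rate), c(100, 0, 0))
})

test_that("confusion matrix marginals match the test composition", {
  tab <- small_feature_table()
  sp <- stratified_split(tab, seed = 2)
  ev <- evaluate_grading(sp$train, sp$test, reducer = "lda", seed = 1,
                         tune_args = list(k_grid = 5, sigma_mult = 1,
                                          C_grid = 1, folds = 3))
  expect_equal(unname(rowSums(ev$confusion)),
               as.vector(table(sp$test$grade)))
  expect_equal(sum(ev$confusion), nrow(sp$test))
  expect_equal(ev$overall_rate, 100 * sum(diag(ev$confusion)) / sum(ev$confusion))
  expect_equal(ev$average_rate,
               mean(100 * diag(ev$confusion) / rowSums(ev$confusion)))
  expect_equal(tidy(ev)$n_test, unname(rowSums(ev$confusion)))
  expect_equal(glance(ev)$feature_space, "lda")
  expect_s3_class(autoplot(ev), "ggplot")
  expect_output(print(ev), "average recognition rate")
})

test_that("the reducer is fitted on the training partition only", {
  tab <- small_feature_table()
  sp <- stratified_split(tab, seed = 3)
  ev <- evaluate_grading(sp$train, sp$test, reducer = "pca",
                         classifier = function(train, test, label_col)
                           as.character(test[[label_col]]))
  oracle <- fit_pca(sp$train)
  expect_equal(ev$reducer_model$mean, oracle$mean)
  expect_equal(ev$reducer_model$rotation, oracle$rotation)
})

test_that("overlapping train and test partitions are rejected", {
  tab <- small_feature_table()
  expect_error(evaluate_grading(tab, tab[1:5, ], reducer = "none"),
               "disjoint")
  expect_error(evaluate_grading(tab[1:40, ], tab[41:60, ],
                                classifier = "nope", reducer = "none"),
               "unknown classifier")
})

test_that("baseline classifiers run and score well on separable clusters", {
  skip_if_not_installed("class")
  skip_if_not_installed("e1071")
  skip_if_not_installed("rpart")
  skip_if_not_installed("randomForest")
  set.seed(51)
  train <- make_clusters(n_per = 30, sep = 6, sd = 0.8)
  test <- make_clusters(n_per = 10, sep = 6, sd = 0.8)
  for (cl in c("knn", "svm", "tree", "rf")) {
    ev <- evaluate_grading(train, test, reducer = "none", classifier = cl,
                           seed = 1)
    expect_gte(ev$average_rate, 90)
    expect_equal(ev$classifier, cl)
  }
})

test_that("compare_classifiers returns one row per classifier", {
  skip_if_not_installed("class")
  skip_if_not_installed("e1071")
  skip_if_not_installed("rpart")
  skip_if_not_installed("randomForest")
  set.seed(53)
  train <- make_clusters(n_per = 25, sep = 5, sd = 1)
  test <- make_clusters(n_per = 8, sep = 5, sd = 1)
  tab <- compare_classifiers(train, test, reducers = "none", seed = 1,
                             tune_args = list(k_grid = 5, sigma_mult = 1,
                                              C_grid = 1, folds = 3))
  expect_equal(tab$classifier, c("knn_svm", "knn", "svm", "tree", "rf"))
  expect_true(all(is.na(tab$error)))
  expect_true(all(tab$average_rate >= 80))
  expect_true(all(tab$best_feature_space == "none"))
})

test_that("a failing feature space is reported per row, not fatally", {
  set.seed(55)
  train <- make_clusters(n_per = 10, labels = "L1")
  test <- make_clusters(n_per = 4, labels = "L1")
  tab <- compare_classifiers(train, test, reducers = "lda", seed = 1)
  expect_equal(nrow(tab), 5)
  expect_true(all(!is.na(tab$error)))
  expect_true(all(is.na(tab$average_rate)))
})

test_that("the end-to-end pipeline returns a seeded, reproducible report", {
  small_tune <- list(k_grid = 3, sigma_mult = 1, C_grid = 1, folds = 3)
  e1 <- run_grading_pipeline(seed = 6, reducer = "lda",
                             n_apples_per_grade = 3, recordings_per_apple = 2,
                             config = recording_config(duration_s = 40),
                             tune_args = small_tune)
  e2 <- run_grading_pipeline(seed = 6, reducer = "lda",
                             n_apples_per_grade = 3, recordings_per_apple = 2,
                             config = recording_config(duration_s = 40),
                             tune_args = small_tune)
  expect_s3_class(e1, "grading_eval")
  expect_equal(e1$confusion, e2$confusion)
  expect_equal(e1$average_rate, e2$average_rate)
  expect_equal(e1$n_train + e1$n_test, 18)
})
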