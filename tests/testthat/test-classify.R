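test_that("stratified split honors largest-remainder sizes and determinism", {
  # 100 rows, 20 positive: exact proportions per split and class
  y <- rep(c(1, 0), c(20, 80))
  sp <- stratified_split(y, seed = 3)
  expect_equal(unname(lengths(sp)), c(80L, 15L, 5L))
  expect_equal(unname(vapply(sp, function(i) sum(y[i]), 0)), c(16, 3, 1))
  expect_equal(sort(unname(unlist(sp))), 1:100)  # disjoint and exhaustive
  # 46 rows: 36.8 / 6.9 / 2.3 rounds to 37 / 7 / 2 by largest remainder
  y46 <- rep(c(0, 1), each = 23)
  sp46 <- stratified_split(y46, seed = 3)
  expect_equal(unname(lengths(sp46)), c(37L, 7L, 2L))
  # determinism
  expect_identical(stratified_split(y, seed = 11), stratified_split(y, seed = 11))
  # a test split without one class is absorbed into validation, with warning
  y_imb <- rep(c(0, 1), c(34, 12))
  expect_warning(sp_m <- stratified_split(y_imb, seed = 3), "merging")
  expect_length(sp_m$test, 0)
  expect_equal(sort(unname(unlist(sp_m))), 1:46)
  expect_error(stratified_split(rep(1, 10)), class = "degenerate_labels")
})

test_that("boosting reproduces the closed-form round arithmetic", {
  # separable 1-D data: one stump suffices, training accuracy 1
  X <- matrix(c(-3, -2, -1, 1, 2, 3), ncol = 1)
  y <- as.integer(X[, 1] > 0)
  model <- train_adaboost(X, y, boost_params(n_learners = 10, feature_subset = "all"))
  expect_length(model$learners, 1)   # perfect round stops training
  expect_equal(predict(model, X), y)
  # one misclassified point at uniform weights, n = 4: eps 0.25,
  # alpha = 0.1 * ln 3; the misclassified weight rises above 1/4
  eps <- 0.25
  alpha <- 0.1 * log((1 - eps) / eps)
  expect_equal(alpha, 0.1 * log(3))
  w <- rep(0.25, 4)
  w[4] <- w[4] * exp(alpha)
  w <- w / sum(w)
  expect_gt(w[4], 0.25)
  expect_true(all(w[1:3] < 0.25))
  expect_equal(alpha, 0.10986, tolerance = 1e-4)
})

test_that("ensemble voting follows weighted signs with ties to non-faulty", {
  stump <- function(cls) list(leaf = TRUE, class = cls)
  mk <- function(alphas, classes) {
    structure(list(learners = lapply(classes, stump), alphas = alphas,
                   features = "f", n_features = 1L, params = NULL),
              class = "adaboost_model")
  }
  X <- matrix(0, 3, 1)
  # single learner: its vote
  expect_equal(predict(mk(1, list(1L)), X), rep(1L, 3))
  # alphas (1.0, 0.4) voting (1, 0): net +0.6 -> class 1
  expect_equal(predict(mk(c(1, 0.4), list(1L, 0L)), X), rep(1L, 3))
  # all-zero alphas: tie -> class 0
  expect_equal(predict(mk(c(0, 0), list(1L, 0L)), X), rep(0L, 3))
  expect_error(predict(mk(1, list(1L)), matrix(0, 2, 3)), class = "shape_error")
})

test_that("tree depth stays bounded and training needs both classes", {
  set.seed(201)
  X <- matrix(stats::rnorm(60 * 4), 60, 4)
  y <- as.integer(X[, 1] + X[, 2] > 0)
  model <- train_adaboost(X, y, boost_params(n_learners = 15, max_depth = 3))
  depths <- vapply(model$learners, motionscreen:::tree_depth, 0L)
  expect_true(all(depths <= 3))
  expect_equal(length(model$learners), length(model$alphas))
  expect_error(train_adaboost(X, rep(1L, 60)), class = "degenerate_labels")
})

test_that("row permutation leaves predictions unchanged for a fixed schedule", {
  set.seed(202)
  X <- matrix(stats::rnorm(40 * 5), 40, 5)
  y <- as.integer(X[, 2] - X[, 4] > 0)
  Xnew <- matrix(stats::rnorm(10 * 5), 10, 5)
  p <- sample(40)
  params <- boost_params(n_learners = 20, seed = 7)
  m1 <- train_adaboost(X, y, params)
  m2 <- train_adaboost(X[p, ], y[p], params)
  expect_equal(predict(m1, Xnew), predict(m2, Xnew))
})

test_that("evaluation reports the confusion ratios and flags undefined ones", {
  # TP 3, FN 1, TN 30, FP 2
  y_true <- c(rep(1, 4), rep(0, 32))
  y_pred <- c(1, 1, 1, 0, rep(0, 30), 1, 1)
  ev <- evaluate_classifier(y_true, y_pred)
  expect_equal(unname(ev$confusion), c(3L, 2L, 30L, 1L))
  expect_equal(ev$sensitivity, 0.75)
  expect_equal(ev$specificity, 0.9375)
  expect_equal(ev$accuracy, 33 / 36)
  # perfect predictions
  evp <- evaluate_classifier(c(0, 1, 1), c(0, 1, 1))
  expect_equal(c(evp$sensitivity, evp$specificity, evp$accuracy), c(1, 1, 1))
  # no positives in the test set: sensitivity undefined, flagged
  ev0 <- evaluate_classifier(c(0, 0), c(0, 1))
  expect_true(is.nan(ev0$sensitivity))
  expect_equal(ev0$undefined, "sensitivity")
})

test_that("boosted ensembles match the exhaustive-stump reference label-for-label", {
  set.seed(203)
  cases <- 0L
  for (n in 2:8) {
    for (rep in 1:25) {
      X <- matrix(round(stats::rnorm(n * 2), 2), n, 2)
      y <- stats::rbinom(n, 1, 0.5)
      if (length(unique(y)) < 2) next
      Xnew <- matrix(round(stats::rnorm(12), 2), 6, 2)
      params <- boost_params(n_learners = 8, learning_rate = 1, max_depth = 1,
                             feature_subset = "all")
      mine <- tryCatch(predict(train_adaboost(X, y, params), Xnew),
                       motionscreen_error = function(e) rep(0L, nrow(Xnew)))
      ref <- oracle_adaboost_predict(X, y, Xnew, n_rounds = 8, learning_rate = 1)
      expect_identical(mine, ref)
      cases <- cases + 1L
    }
  }
  expect_gt(cases, 100L)
})

test_that("ensemble training error does not exceed the best single stump", {
  set.seed(204)
  X <- matrix(stats::rnorm(30 * 2), 30, 2)
  y <- as.integer(X[, 1] > 0.2)
  params1 <- boost_params(n_learners = 1, learning_rate = 1, max_depth = 1,
                          feature_subset = "all")
  params20 <- boost_params(n_learners = 20, learning_rate = 1, max_depth = 1,
                           feature_subset = "all")
  err <- function(p) mean(predict(train_adaboost(X, y, p), X) != y)
  expect_lte(err(params20), err(params1))
})

test_that("model JSON serialization round-trips predictions", {
  set.seed(205)
  X <- matrix(stats::rnorm(50 * 6), 50, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  y <- as.integer(X[, 1] + 0.5 * X[, 3] > 0)
  model <- train_adaboost(X, y, boost_params(n_learners = 12))
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_model_json(model, path)
  back <- read_model_json(path)
  expect_equal(back$alphas, model$alphas)
  expect_identical(predict(back, X), predict(model, X))
})

test_that("cross-validation pools out-of-fold predictions deterministically", {
  set.seed(206)
  X <- matrix(stats::rnorm(60 * 4), 60, 4)
  y <- as.integer(X[, 1] > 0)
  cv1 <- cross_validate_adaboost(X, y, boost_params(n_learners = 10, seed = 5), k = 5)
  cv2 <- cross_validate_adaboost(X, y, boost_params(n_learners = 10, seed = 5), k = 5)
  expect_identical(cv1$predictions, cv2$predictions)
  expect_equal(sort(unique(cv1$folds)), 1:5)
  expect_gt(cv1$metrics$accuracy, 0.8)  # trivially separable signal
})
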