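test_that("parameter count matches direct summation for arbitrary layers", {
  set.seed(3)
  for (i in 1:20) {
    widths <- sample(1:50, sample(2:6, 1), replace = TRUE)
    direct <- 0
    for (l in seq_len(length(widths) - 1L))
      direct <- direct + widths[l] * widths[l + 1L] + widths[l + 1L]
    expect_equal(countParameters(widths), direct)
  }
  expect_error(countParameters(c(10, 0, 1)), "widths")
})

test_that("network construction and activations behave as specified", {
  spec <- networkSpec(4, c(3L, 2L), 0, "classification")
  m <- buildDNN(spec, seed = 1L)
  expect_equal(dim(m@weights[[1]]), c(3, 4))
  expect_equal(dim(m@weights[[3]]), c(1, 2))
  expect_error(networkSpec(4, c(3L, 0L)), "widths")

  ## zero all parameters: every pre-activation is 0, so the sigmoid head
  ## returns exactly 0.5 and the linear head exactly 0
  m@weights <- lapply(m@weights, function(w) w * 0)
  expect_equal(predict(m, matrix(rnorm(8), 2, 4)), c(0.5, 0.5))
  mr <- buildDNN(networkSpec(4, c(3L, 2L), 0, "regression"), seed = 1L)
  mr@weights <- lapply(mr@weights, function(w) w * 0)
  expect_equal(predict(mr, matrix(rnorm(8), 2, 4)), c(0, 0))

  ## ReLU clamps negatives and passes positives
  expect_equal(SynergyNet:::.relu(c(-3, 2)), c(0, 2))
  expect_equal(SynergyNet:::.sigmoid(0), 0.5)
})

test_that("training reduces loss, memorizes small data, and is seeded", {
  set.seed(5)
  x <- matrix(rnorm(50 * 6), 50, 6)
  y <- x %*% c(1, -2, 0.5, 0, 1, -1) + 0.3
  cfg <- trainingConfig("regression", optimizer = "adam",
                        learningRate = 5e-3, batchSize = 10L,
                        epochs = 200L, seed = 9L)
  m <- trainDNN(networkSpec(6, c(16L, 8L), 0), x, y, cfg)
  h <- trainingHistory(m)
  expect_lt(h$loss[nrow(h)], h$loss[1])

  ## 8-sample toy, no dropout: the network memorizes
  x8 <- matrix(rnorm(8 * 3), 8, 3)
  y8 <- rnorm(8)
  cfg8 <- trainingConfig("regression", optimizer = "adam",
                         learningRate = 1e-2, batchSize = 8L,
                         epochs = 1500L, seed = 2L)
  m8 <- trainDNN(networkSpec(3, c(32L, 16L), 0), x8, y8, cfg8)
  expect_lt(mean((predict(m8, x8) - y8)^2), 1e-2)
  ## memorized predictions approximate the training labels themselves
  expect_equal(predict(m8, x8), as.numeric(y8), tolerance = 0.1)

  ## identical seeds give bit-identical loss histories
  m2 <- trainDNN(networkSpec(6, c(16L, 8L), 0), x, y, cfg)
  expect_identical(trainingHistory(m)$loss, trainingHistory(m2)$loss)

  ## divergence is reported, not silently propagated
  expect_error(
    trainDNN(networkSpec(6, c(16L, 8L), 0), x * 1e3, y * 1e3,
             trainingConfig("regression", optimizer = "sgd",
                            learningRate = 1e6, batchSize = 50L,
                            epochs = 50L, seed = 1L)),
    "diverged")
})

test_that("full-batch training loss is monotone non-increasing after burn-in", {
  set.seed(8)
  x <- matrix(rnorm(40 * 4), 40, 4)
  y <- as.numeric(x %*% c(2, -1, 1, 0.5))   # noiseless linear target
  cfg <- trainingConfig("regression", optimizer = "adam",
                        learningRate = 2e-3, batchSize = 40L,
                        epochs = 150L, seed = 4L)
  h <- trainingHistory(trainDNN(networkSpec(4, c(8L, 4L), 0), x, y, cfg))
  after <- h$loss[10:nrow(h)]
  expect_true(all(diff(after) <= 1e-6))
})

test_that("classification training yields calibrated scores in [0, 1]", {
  set.seed(11)
  x <- matrix(rnorm(60 * 4), 60, 4)
  y <- as.integer(x[, 1] + x[, 2] > 0)
  cfg <- trainingConfig("classification", learningRate = 5e-3,
                        batchSize = 20L, epochs = 150L, seed = 3L)
  m <- trainDNN(networkSpec(4, c(8L, 4L), 0, "classification"), x, y, cfg)
  p <- predict(m, x)
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(mean((p >= 0.5) == y), 0.8)
  expect_identical(predict(m, x), p)   # inference is deterministic
})

test_that("baseline defaults echo the documented optima", {
  expect_equal(baselineDefaults("knn", "regression")$k, 6L)
  expect_equal(baselineDefaults("knn", "classification")$k, 5L)
  expect_equal(baselineDefaults("rf", "regression"),
               list(ntree = 200L, min_samples_leaf = 50L))
  expect_equal(baselineDefaults("rf", "classification"),
               list(ntree = 100L, min_samples_leaf = 10L))
  expect_equal(baselineDefaults("svm", "regression"),
               list(kernel = "radial", cost = 10, gamma = 0.01))
  expect_equal(baselineDefaults("svm", "classification"),
               list(kernel = "radial", cost = 1, gamma = 0.1))
  expect_equal(baselineDefaults("gbm", "regression"),
               list(n_estimators = 500L, min_samples_split = 1000L,
                    learning_rate = 0.01, min_samples_leaf = 60L))
  expect_equal(baselineDefaults("gbm", "classification")$n_estimators, 200L)
})

test_that("uniform KNN regression averages the k nearest labels", {
  x <- matrix(c(0, 1, 2, 3, 4, 5, 100), ncol = 1)
  y <- c(10, 20, 30, 40, 50, 60, 1000)
  m <- trainBaseline(x, y, "knn", "regression", params = list(k = 6L))
  ## query at 2.4: the 6 nearest are the first six points
  expect_equal(predict(m, matrix(2.4)), mean(y[1:6]))
  expect_error(trainBaseline(x, y, "knn", params = list(k = 10L)), "exceeds")
})

test_that("all model families satisfy the shared predict contract", {
  set.seed(21)
  x <- matrix(rnorm(60 * 5), 60, 5)
  colnames(x) <- paste0("f", 1:5)
  yreg <- as.numeric(x %*% rnorm(5))
  ycls <- as.integer(x[, 1] > 0)
  small_dnn <- function(task) {
    cfg <- trainingConfig(task, learningRate = 5e-3, batchSize = 20L,
                          epochs = 30L, seed = 1L)
    trainDNN(networkSpec(5, c(8L, 4L), 0, task), x,
             if (task == "regression") yreg else ycls, cfg)
  }
  models_reg <- c(lapply(c("knn", "rf", "svm", "gbm"), function(f)
    trainBaseline(x, yreg, f, "regression",
                  params = utils::modifyList(baselineDefaults(f, "regression"),
                                             list(min_samples_leaf = 2L,
                                                  min_samples_split = 4L)))),
    list(small_dnn("regression")))
  for (m in models_reg) {
    p <- predict(m, x)
    expect_length(p, 60)
    expect_true(all(is.finite(p)))
  }
  models_cls <- c(lapply(c("knn", "rf", "svm", "gbm"), function(f)
    trainBaseline(x, ycls, f, "classification",
                  params = utils::modifyList(baselineDefaults(f, "classification"),
                                             list(min_samples_leaf = 2L,
                                                  min_samples_split = 4L)))),
    list(small_dnn("classification")))
  for (m in models_cls) {
    p <- predict(m, x)
    expect_true(all(p >= 0 & p <= 1))
  }

  ## seeded RF is reproducible
  r1 <- trainBaseline(x, yreg, "rf", params = list(ntree = 50L, min_samples_leaf = 2L), seed = 5L)
  r2 <- trainBaseline(x, yreg, "rf", params = list(ntree = 50L, min_samples_leaf = 2L), seed = 5L)
  expect_identical(predict(r1, x), predict(r2, x))

  ## dimension mismatches name expected and actual
  expect_error(predict(models_reg[[2]], x[, 1:3]), "5.*3")
})

test_that("grid search enumerates the product and breaks ties first-wins", {
  set.seed(2)
  x <- matrix(rnorm(40 * 3), 40, 3)
  y <- as.numeric(x %*% c(1, 2, -1))
  gs <- gridSearchCV(x, y, family = "knn",
                     grids = list(k = c(2L, 4L), weights = c("uniform")),
                     folds = 4L, task = "regression", seed = 1L)
  expect_equal(nrow(gs$table), 2L)
  expect_true(gs$best$k %in% c(2L, 4L))
  expect_equal(gs$bestScore, min(gs$table$score))

  ## duplicated grid point: identical scores, first config returned
  gs2 <- gridSearchCV(x, y, family = "knn",
                      grids = list(k = c(3L, 3L)), folds = 4L, seed = 1L)
  expect_equal(gs2$table$score[1], gs2$table$score[2])
  expect_identical(which(gs2$table$score == gs2$bestScore)[1], 1L)

  ## single-point grid returns that configuration unchanged
  gs3 <- gridSearchCV(x, y, family = "knn", grids = list(k = 5L),
                      folds = 4L, seed = 1L)
  expect_equal(gs3$best$k, 5L)

  expect_error(gridSearchCV(x, y, "knn", list(k = 2L), folds = 1L), "folds")
  expect_error(gridSearchCV(x, y, "knn", list(k = integer(0)), folds = 2L),
               "non-empty")
})

test_that("model save/load round-trips predictions exactly", {
  set.seed(6)
  x <- matrix(rnorm(20 * 4), 20, 4)
  y <- rnorm(20)
  cfg <- trainingConfig("regression", learningRate = 1e-2, batchSize = 10L,
                        epochs = 20L, seed = 7L)
  m <- trainDNN(networkSpec(4, c(6L, 3L), 0), x, y, cfg)
  dir <- withr::local_tempdir()
  saveDNNModel(m, dir)
  m2 <- loadDNNModel(dir)
  expect_identical(predict(m2, x), predict(m, x))
  expect_equal(trainingHistory(m2)$loss, trainingHistory(m)$loss)
})
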