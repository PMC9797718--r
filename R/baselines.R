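#' Printed-optimum default hyperparameters for the baseline learners
#'
#' Defaults echo each family's optimized settings: KNN regression 6
#' neighbors / classification 5, both uniform weights; RF regression 200
#' trees with minimum leaf size 50 / classification 100 trees, leaf 10;
#' SVM RBF kernel with C=10, gamma=0.01 (regression) and C=1, gamma=0.1
#' (classification); GBM regression 500 trees, minimum split 1000,
#' learning rate 0.01, minimum leaf 60 / classification 200 trees, split
#' 600, rate 0.01, leaf 60.
#'
#' @param family `"knn"`, `"rf"`, `"svm"` or `"gbm"`.
#' @param task `"regression"` or `"classification"`.
#' @return named list of hyperparameters.
#' @export
baselineDefaults <- function(family = c("knn", "rf", "svm", "gbm"),
                             task = c("regression", "classification")) {
  family <- match.arg(family); task <- match.arg(task)
  reg <- task == "regression"
  switch(family,
    knn = list(k = if (reg) 6L else 5L, weights = "uniform"),
    rf  = list(ntree = if (reg) 200L else 100L,
               min_samples_leaf = if (reg) 50L else 10L),
    svm = list(kernel = "radial", cost = if (reg) 10 else 1,
               gamma = if (reg) 0.01 else 0.1),
    gbm = list(n_estimators = if (reg) 500L else 200L,
               min_samples_split = if (reg) 1000L else 600L,
               learning_rate = 0.01, min_samples_leaf = 60L))
}

#' Train a classical baseline model
#'
#' All four families expose the same predict contract as the network:
#' regression yields real-valued scores, classification yields scores in
#' `[0, 1]`. KNN stores its training set (uniform-weight neighbor
#' averaging); RF uses `randomForest`; SVM uses `e1071` with an RBF
#' kernel; GBM uses `xgboost` (minimum split/leaf sizes mapped to
#' `min_child_weight`).
#'
#' @param x samples-in-rows matrix or [SampleSet-class].
#' @param y labels (taken from the SampleSet if omitted).
#' @param family `"knn"`, `"rf"`, `"svm"` or `"gbm"`.
#' @param task `"regression"` or `"classification"`.
#' @param params hyperparameters; defaults to [baselineDefaults()].
#' @param seed integer seed for the stochastic families.
#' @return a [BaselineModel-class].
#' @export
trainBaseline <- function(x, y = NULL, family = c("knn", "rf", "svm", "gbm"),
                          task = c("regression", "classification"),
                          params = NULL, seed = 1L) {
  family <- match.arg(family); task <- match.arg(task)
  if (is(x, "SampleSet")) {
    if (is.null(y)) y <- sampleLabels(x, task)
    featnames <- rownames(SummarizedExperiment::assay(x))
    x <- featureMatrix(x)
  } else featnames <- colnames(x)
  x <- as.matrix(x); y <- as.numeric(y)
  if (length(y) != nrow(x)) stop("label length does not match sample count")
  if (task == "classification" && !all(y %in% c(0, 1)))
    stop("classification labels must be 0/1")
  if (is.null(params)) params <- baselineDefaults(family, task)

  fit <- switch(family,
    knn = {
      if (params$k > nrow(x))
        stop("k = ", params$k, " exceeds training size ", nrow(x))
      list(x = x, y = y, k = as.integer(params$k))
    },
    rf = .with_seed(seed, {
      yy <- if (task == "classification") factor(y, levels = c(0, 1)) else y
      randomForest::randomForest(x, yy, ntree = params$ntree,
                                 nodesize = params$min_samples_leaf)
    }),
    svm = .with_seed(seed, {
      yy <- if (task == "classification") factor(y, levels = c(0, 1)) else y
      e1071::svm(x, yy, kernel = params$kernel, cost = params$cost,
                 gamma = params$gamma, scale = FALSE,
                 probability = task == "classification")
    }),
    gbm = .with_seed(seed, {
      obj <- if (task == "classification") "binary:logistic" else "reg:squarederror"
      dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1L)
      xgboost::xgb.train(
        params = list(objective = obj, eta = params$learning_rate,
                      min_child_weight = max(params$min_samples_leaf, 1L),
                      nthread = 1L),
        data = dtrain, nrounds = params$n_estimators, verbose = 0)
    }))
  new("BaselineModel", family = family, task = task, fit = fit,
      params = params, featureNames = as.character(featnames %||% character()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @describeIn trainBaseline predict scores from a fitted baseline.
#' @param object a [BaselineModel-class].
#' @param newdata samples-in-rows matrix or [SampleSet-class].
#' @param ... ignored.
#' @export
setMethod("predict", "BaselineModel", function(object, newdata, ...) {
  x <- if (is(newdata, "SampleSet")) featureMatrix(newdata) else as.matrix(newdata)
  nexp <- if (length(object@featureNames)) length(object@featureNames) else NA
  if (!is.na(nexp) && ncol(x) != nexp)
    stop("dimension mismatch: model expects ", nexp, " features, got ", ncol(x))
  .check_predict_input(object@featureNames, x)
  out <- switch(object@family,
    knn = {
      tr <- object@fit
      if (object@task == "regression")
        FNN::knn.reg(train = tr$x, test = x, y = tr$y, k = tr$k)$pred
      else {
        cl <- class::knn(train = tr$x, test = x, cl = factor(tr$y),
                         k = tr$k, prob = TRUE)
        pwin <- attr(cl, "prob")
        ifelse(cl == "1", pwin, 1 - pwin)  # P(class 1)
      }
    },
    rf = {
      if (object@task == "regression") predict(object@fit, x)
      else predict(object@fit, x, type = "prob")[, "1"]
    },
    svm = {
      if (object@task == "regression") predict(object@fit, x)
      else {
        p <- predict(object@fit, x, probability = TRUE)
        attr(p, "probabilities")[, "1"]
      }
    },
    gbm = predict(object@fit, xgboost::xgb.DMatrix(x, nthread = 1L)))
  as.numeric(out)
})

#' Exhaustive grid search with k-fold cross-validation
#'
#' Every configuration in the Cartesian product of the supplied grids is
#' evaluated by k-fold cross-validation (seeded shuffle, then contiguous
#' blocks). Regression selects the minimum mean validation MSE;
#' classification the maximum mean validation accuracy (score threshold
#' 0.5). Ties break deterministically to the first configuration in
#' product order.
#'
#' @param x,y training features and labels (or a [SampleSet-class]).
#' @param family `"dnn"`, `"knn"`, `"rf"`, `"svm"` or `"gbm"`.
#' @param grids named list of parameter vectors. For the network:
#'   `epochs`, `batchSize`, `learningRate`, `dropoutRate`, `hidden1`,
#'   `hidden2`. For baselines: the [baselineDefaults()] names.
#' @param folds number of CV folds (>= 2).
#' @param task `"regression"` or `"classification"`.
#' @param seed integer seed for fold assignment and model fits.
#' @return list with `best` (named parameter list), `bestScore`, and
#'   `table` (one row per configuration with the mean CV score).
#' @export
gridSearchCV <- function(x, y = NULL, family = "dnn", grids, folds = 10L,
                         task = "regression", seed = 1L) {
  if (is(x, "SampleSet")) {
    if (is.null(y)) y <- sampleLabels(x, task)
    x <- featureMatrix(x)
  }
  x <- as.matrix(x); y <- as.numeric(y)
  if (folds < 2L) stop("folds must be >= 2")
  if (!length(grids) || any(!vapply(grids, length, 1L)))
    stop("every grid must be non-empty")
  n <- nrow(x)
  if (n < folds) stop("fewer samples than folds")

  ## seeded shuffle, then contiguous blocks along the shuffled order
  fold_id <- .with_seed(seed, {
    id <- integer(n)
    id[sample.int(n)] <- as.integer(cut(seq_len(n), breaks = folds, labels = FALSE))
    id
  })

  configs <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  scores <- numeric(nrow(configs))
  for (i in seq_len(nrow(configs))) {
    cfg <- as.list(configs[i, , drop = FALSE])
    fold_scores <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f; va <- !tr
      pred <- .fit_predict_config(family, cfg, x[tr, , drop = FALSE], y[tr],
                                  x[va, , drop = FALSE], task, seed)
      if (task == "regression") mean((pred - y[va])^2)
      else mean((pred >= 0.5) == y[va])
    }, numeric(1))
    scores[i] <- mean(fold_scores)
  }
  best_i <- if (task == "regression") which.min(scores) else which.max(scores)
  list(best = as.list(configs[best_i, , drop = FALSE]),
       bestScore = scores[best_i],
       table = cbind(configs,
                     score = scores,
                     metric = if (task == "regression") "cv_mse" else "cv_accuracy"))
}

.fit_predict_config <- function(family, cfg, xtr, ytr, xva, task, seed) {
  if (family == "dnn") {
    hidden <- c(cfg$hidden1 %||% 200L, cfg$hidden2 %||% 100L)
    spec <- networkSpec(ncol(xtr), hidden, cfg$dropoutRate %||% 0.5, task)
    config <- trainingConfig(task,
                             learningRate = cfg$learningRate %||% NULL,
                             batchSize = cfg$batchSize %||% NULL,
                             epochs = cfg$epochs %||% NULL, seed = seed)
    model <- trainDNN(spec, xtr, ytr, config)
  } else {
    params <- utils::modifyList(baselineDefaults(family, task), cfg)
    model <- trainBaseline(xtr, ytr, family, task, params, seed)
  }
  predict(model, xva)
}

#' Default network hyperparameter grids
#'
#' Ships the reference search space with level counts 5, 5, 3, 3, 5, 5
#' (epochs, batch size, learning rate, dropout rate, first and second
#' hidden width), whose Cartesian product enumerates 5,625 candidate
#' configurations.
#'
#' @param task `"regression"` or `"classification"` (same shape either way).
#' @return named list of parameter vectors.
#' @examples
#' prod(lengths(defaultGrids()))  # 5625
#' @export
defaultGrids <- function(task = "regression") {
  list(epochs = c(50L, 100L, 200L, 300L, 500L),
       batchSize = c(16L, 32L, 64L, 128L, 256L),
       learningRate = c(1e-5, 1e-4, 1e-3),
       dropoutRate = c(0, 0.25, 0.5),
       hidden1 = c(50L, 100L, 150L, 200L, 300L),
       hidden2 = c(25L, 50L, 100L, 150L, 200L))
}
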