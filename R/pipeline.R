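#' Train a predictor on a synthetic world's monotherapy screen
#'
#' Convenience pipeline: assembles samples from the world's expression
#' matrix, target map and monotherapy responses, splits them, fits the
#' standardizer on the training split only, and trains the requested
#' model. The network defaults here are small-data settings (two modest
#' hidden layers, no dropout, Adam at 1e-3) suited to screens of a few
#' hundred samples; see [networkSpec()]/[trainingConfig()] for the
#' large-screen defaults.
#'
#' @param world a [generateWorld()] result.
#' @param responses a [generateResponses()] result.
#' @param model `"dnn"`, `"knn"`, `"rf"`, `"svm"` or `"gbm"`.
#' @param task `"regression"` or `"classification"`.
#' @param hiddenUnits,dropoutRate,learningRate,batchSize,epochs network
#'   settings (ignored for baselines).
#' @param trainFraction,seed split and training seeds.
#' @param classThreshold,thresholdUnit positive-class rule for
#'   classification labels (default 1 uM here: the synthetic world's
#'   potency scale is micromolar).
#' @return list with `model`, `standardizer`, `schema`, `split` (train /
#'   test SampleSets, standardized), and `metrics` on the test split.
#' @export
trainWorldModel <- function(world, responses, model = "dnn",
                            task = "regression",
                            hiddenUnits = c(64L, 32L), dropoutRate = 0,
                            learningRate = 1e-3, batchSize = 32L,
                            epochs = 300L, trainFraction = 0.8, seed = 1L,
                            classThreshold = 1, thresholdUnit = "uM") {
  samples <- assembleSamples(world$expression, world$targetMap,
                             responses$monotherapy, world$schema,
                             classThreshold = classThreshold,
                             thresholdUnit = thresholdUnit)
  split <- splitDataset(samples, trainFraction, seed)
  std <- fitStandardizer(split$train)
  train_z <- applyStandardizer(std, split$train)
  test_z <- applyStandardizer(std, split$test)

  fitted <- if (model == "dnn") {
    spec <- networkSpec(featureDim(world$schema), hiddenUnits, dropoutRate, task)
    cfg <- trainingConfig(task, optimizer = "adam",
                          learningRate = learningRate,
                          batchSize = batchSize, epochs = epochs, seed = seed)
    trainDNN(spec, train_z, config = cfg)
  } else {
    trainBaseline(train_z, family = model, task = task, seed = seed)
  }
  scores <- predict(fitted, test_z)
  ## a degenerate test split (e.g. single-class labels) yields NULL metrics
  ## rather than aborting the whole pipeline
  metrics <- tryCatch(metricReport(sampleLabels(test_z, task), scores, task),
                      error = function(e) NULL)
  list(model = fitted, standardizer = std, schema = world$schema,
       split = list(train = train_z, test = test_z),
       metrics = metrics)
}

#' Ranking recovery against synthetic ground truth
#'
#' Ranks candidate combinations in every cell line with the trained model
#' and correlates the predicted pseudo-IC50s with the true combination
#' log-IC50s (Spearman, per cell line). High recovery means the
#' monotherapy-trained model orders unseen multi-drug combinations the
#' way the generative truth does.
#'
#' @param world,responses the synthetic world and its
#'   [generateResponses()] result (`combinationTruth` supplies the
#'   ground truth).
#' @param model,standardizer a trained predictor and the training-split
#'   standardizer (e.g. from [trainWorldModel()]).
#' @return list with `perCellLine` (named Spearman vector; NA for cell
#'   lines whose true ranking is constant and therefore uninformative) and
#'   `mean` (over informative cell lines).
#' @export
evaluateRankingRecovery <- function(world, responses, model, standardizer) {
  truth <- responses$combinationTruth
  combos <- strsplit(unique(truth$combination_id), ";", fixed = TRUE)
  rho <- vapply(rownames(world$activity), function(cl) {
    tab <- rankCombinations(model, world$expression, cl, combos,
                            world$targetMap, world$schema, standardizer)
    tcl <- truth[truth$cell_line_id == cl, ]
    m <- match(tab$combination_id, tcl$combination_id)
    truth_cl <- tcl$true_log_ic50[m]
    if (stats::sd(truth_cl) == 0) return(NA_real_)
    stats::cor(tab$pseudo_ic50, truth_cl, method = "spearman")
  }, numeric(1))
  list(perCellLine = rho, mean = mean(rho, na.rm = TRUE))
}
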