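#' @import methods
#' @importFrom stats predict
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors metadata DataFrame
NULL

#' FeatureSchema: the fixed layout of modeling feature vectors
#'
#' A schema pins down the ordered gene panel (the expression block) and the
#' ordered target universe (the binary drug-target block). Every sample
#' vector is laid out as `[expression block || target block]`, so the total
#' feature dimension is `length(genePanel) + length(targetUniverse)`.
#'
#' @slot genePanel ordered character vector of gene symbols.
#' @slot targetUniverse ordered character vector of target identifiers.
#' @export
setClass("FeatureSchema",
  representation(genePanel = "character", targetUniverse = "character"))

setValidity("FeatureSchema", function(object) {
  msg <- NULL
  if (length(object@genePanel) == 0L) msg <- c(msg, "gene panel is empty")
  if (length(object@targetUniverse) == 0L) msg <- c(msg, "target universe is empty")
  if (anyDuplicated(object@genePanel))
    msg <- c(msg, "duplicate symbols in gene panel")
  if (anyDuplicated(object@targetUniverse))
    msg <- c(msg, "duplicate identifiers in target universe")
  if (is.null(msg)) TRUE else msg
})

#' Construct a FeatureSchema
#'
#' @param genePanel character vector of gene symbols (order defines the
#'   expression block layout).
#' @param targetUniverse character vector of target identifiers (order
#'   defines the target block layout).
#' @return a [FeatureSchema-class] object.
#' @examples
#' sch <- FeatureSchema(c("TP53", "EGFR"), c("t1", "t2", "t3"))
#' featureDim(sch)  # 5
#' @export
FeatureSchema <- function(genePanel, targetUniverse) {
  new("FeatureSchema", genePanel = as.character(genePanel),
      targetUniverse = as.character(targetUniverse))
}

#' SampleSet: assembled modeling samples
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding
#' one assembled sample per column. The single assay `"features"` stores the
#' stacked feature vectors (rows = features in schema order, columns =
#' samples); `rowData()$block` marks each row as `"gene"` or `"target"`;
#' `colData()` carries `cell_line`, `combination_id`, `drugs`
#' (semicolon-joined members), `ic50_uM` (raw response in micromolar, NA for
#' prediction-only samples), `label_regression` and `label_class`.
#'
#' @export
setClass("SampleSet", contains = "SummarizedExperiment")

#' Standardizer: per-column location/scale learned on a training split
#'
#' @slot center named numeric vector of per-feature means.
#' @slot scale named numeric vector of per-feature population standard
#'   deviations (0 for constant columns).
#' @slot constant logical vector flagging zero-variance columns, which are
#'   transformed to exactly 0.
#' @export
setClass("Standardizer",
  representation(center = "numeric", scale = "numeric", constant = "logical"))

setValidity("Standardizer", function(object) {
  if (length(object@center) != length(object@scale) ||
      length(object@center) != length(object@constant))
    return("center, scale and constant must have equal length")
  if (any(object@scale < 0)) return("negative scale")
  TRUE
})

#' NetworkSpec: architecture of the feed-forward network
#'
#' The network is a fully connected multilayer perceptron: ReLU hidden
#' layers (`y = ReLU(W x + b)`), inverted dropout after each hidden layer
#' during training, and a scalar output head that is linear for regression
#' or sigmoid for classification.
#'
#' @slot inputDim integer, feature dimension.
#' @slot hiddenUnits integer vector of hidden-layer widths.
#' @slot dropoutRate numeric in `[0, 1)`.
#' @slot task `"regression"` or `"classification"`.
#' @export
setClass("NetworkSpec",
  representation(inputDim = "integer", hiddenUnits = "integer",
                 dropoutRate = "numeric", task = "character"))

setValidity("NetworkSpec", function(object) {
  msg <- NULL
  if (object@inputDim < 1L) msg <- c(msg, "inputDim must be >= 1")
  if (length(object@hiddenUnits) < 1L || any(object@hiddenUnits < 1L))
    msg <- c(msg, "all hidden layer widths must be >= 1")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    msg <- c(msg, "dropoutRate must be in [0, 1)")
  if (!object@task %in% c("regression", "classification"))
    msg <- c(msg, "task must be 'regression' or 'classification'")
  if (is.null(msg)) TRUE else msg
})

#' Construct a NetworkSpec
#'
#' Defaults follow the optimized conic architecture: two hidden layers of
#' 200 and 100 units with dropout 0.5.
#'
#' @param inputDim feature dimension of the inputs.
#' @param hiddenUnits integer vector of hidden widths.
#' @param dropoutRate dropout probability applied after each hidden layer
#'   (training only).
#' @param task `"regression"` (linear output) or `"classification"`
#'   (sigmoid output).
#' @return a [NetworkSpec-class].
#' @examples
#' networkSpec(1308)
#' @export
networkSpec <- function(inputDim, hiddenUnits = c(200L, 100L),
                        dropoutRate = 0.5, task = "regression") {
  new("NetworkSpec", inputDim = as.integer(inputDim),
      hiddenUnits = as.integer(hiddenUnits),
      dropoutRate = as.numeric(dropoutRate), task = task)
}

#' TrainingConfig: optimization settings for the network
#'
#' Regression defaults to Adam with learning rate 1e-5, batch size 128 and
#' 200 epochs; classification to RMSprop with learning rate 1e-3, batch
#' size 32 and 500 epochs. Loss is mean squared error (regression) or mean
#' binary cross-entropy (classification). Plain SGD is available.
#'
#' @slot task,optimizer character.
#' @slot learningRate,batchSize,epochs,seed numeric settings.
#' @export
setClass("TrainingConfig",
  representation(task = "character", optimizer = "character",
                 learningRate = "numeric", batchSize = "integer",
                 epochs = "integer", seed = "integer"))

setValidity("TrainingConfig", function(object) {
  msg <- NULL
  if (!object@task %in% c("regression", "classification"))
    msg <- c(msg, "task must be 'regression' or 'classification'")
  if (!object@optimizer %in% c("adam", "rmsprop", "sgd"))
    msg <- c(msg, "optimizer must be adam, rmsprop or sgd")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (is.null(msg)) TRUE else msg
})

#' @rdname TrainingConfig-class
#' @param task `"regression"` or `"classification"`.
#' @param optimizer `"adam"`, `"rmsprop"` or `"sgd"`; default depends on task.
#' @param learningRate,batchSize,epochs optimization settings; defaults
#'   depend on task (see Details).
#' @param seed integer seed controlling weight initialization, shuffling and
#'   dropout masks.
#' @return a [TrainingConfig-class].
#' @export
trainingConfig <- function(task = "regression", optimizer = NULL,
                           learningRate = NULL, batchSize = NULL,
                           epochs = NULL, seed = 1L) {
  defaults <- if (identical(task, "classification"))
    list(optimizer = "rmsprop", learningRate = 1e-3, batchSize = 32L, epochs = 500L)
  else
    list(optimizer = "adam", learningRate = 1e-5, batchSize = 128L, epochs = 200L)
  new("TrainingConfig", task = task,
      optimizer = if (is.null(optimizer)) defaults$optimizer else optimizer,
      learningRate = if (is.null(learningRate)) defaults$learningRate else as.numeric(learningRate),
      batchSize = as.integer(if (is.null(batchSize)) defaults$batchSize else batchSize),
      epochs = as.integer(if (is.null(epochs)) defaults$epochs else epochs),
      seed = as.integer(seed))
}

#' DNNModel: a (possibly trained) feed-forward network
#'
#' @slot spec the [NetworkSpec-class].
#' @slot weights,biases per-layer parameter lists.
#' @slot history data.frame with per-epoch training loss (empty until
#'   trained).
#' @slot featureNames schema fingerprint; `predict` rejects inputs whose
#'   columns do not match.
#' @slot trained logical.
#' @export
setClass("DNNModel",
  representation(spec = "NetworkSpec", weights = "list", biases = "list",
                 history = "data.frame", featureNames = "character",
                 trained = "logical"))

#' BaselineModel: a fitted classical learner with the shared predict contract
#'
#' @slot family one of `"knn"`, `"rf"`, `"svm"`, `"gbm"`.
#' @slot task `"regression"` or `"classification"`.
#' @slot fit the underlying fitted object (for KNN, the stored training set).
#' @slot params hyperparameter list actually used.
#' @slot featureNames schema fingerprint checked at prediction time.
#' @export
setClass("BaselineModel",
  representation(family = "character", task = "character", fit = "ANY",
                 params = "list", featureNames = "character"))

#' MedianEffectFit: parameters of a fitted median-effect dose-response curve
#'
#' The median-effect model is `fa/fu = (D/Dm)^m`; its linearization
#' `log10(fa/(1-fa)) = m log10(D) - m log10(Dm)` is fitted by least squares.
#' `Dm` is the median-effect dose, i.e. the IC50.
#'
#' @slot dm median-effect dose (input dose unit).
#' @slot m slope (dimensionless).
#' @slot r Pearson correlation of the linearized fit.
#' @slot n number of dose points used.
#' @export
setClass("MedianEffectFit",
  representation(dm = "numeric", m = "numeric", r = "numeric", n = "integer"))

setValidity("MedianEffectFit", function(object) {
  if (!is.finite(object@dm) || object@dm <= 0) return("Dm must be positive")
  if (!is.finite(object@m)) return("slope m must be finite")
  TRUE
})

#' SimConfig: parameters of the synthetic drug-response world
#'
#' See [generateWorld()] for the generative model. Defaults define the
#' reference simulation used throughout the package's validation.
#'
#' @slot nCellLines,nGenes,nTargets,nDrugs,nPathways integer counts.
#' @slot targetsPerDrug integer range (min, max) of targets drawn per drug.
#' @slot pathwaysPerDrug integer range (min, max) of pathways a drug's
#'   targets are drawn from.
#' @slot alpha baseline log-IC50 (natural log of micromolar).
#' @slot beta log-IC50 drop per distinct active pathway covered.
#' @slot gamma extra drop per additional distinct active pathway beyond the
#'   first (the synergy bonus).
#' @slot noiseSd standard deviation of the Gaussian label noise.
#' @slot exprBaseline,exprShift,exprSd expression model: baseline level,
#'   elevation of pathway-member genes in cell lines where the pathway is
#'   active, and Gaussian noise sd.
#' @slot seed integer seed; the whole world is deterministic given the
#'   config.
#' @export
setClass("SimConfig",
  representation(nCellLines = "integer", nGenes = "integer",
                 nTargets = "integer", nDrugs = "integer",
                 nPathways = "integer", targetsPerDrug = "integer",
                 pathwaysPerDrug = "integer", alpha = "numeric",
                 beta = "numeric", gamma = "numeric", noiseSd = "numeric",
                 exprBaseline = "numeric", exprShift = "numeric",
                 exprSd = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- NULL
  for (s in c("nCellLines", "nGenes", "nTargets", "nDrugs", "nPathways"))
    if (slot(object, s) < 1L) msg <- c(msg, paste(s, "must be >= 1"))
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@beta < 0 || object@gamma < 0)
    msg <- c(msg, "beta and gamma must be >= 0")
  if (length(object@targetsPerDrug) != 2L ||
      object@targetsPerDrug[1] > object@targetsPerDrug[2])
    msg <- c(msg, "targetsPerDrug must be an increasing (min, max) pair")
  if (object@nTargets < object@targetsPerDrug[2])
    msg <- c(msg, "nTargets must be >= max targets per drug")
  if (is.null(msg)) TRUE else msg
})

#' @rdname SimConfig-class
#' @param nCellLines,nGenes,nTargets,nDrugs,nPathways world dimensions.
#' @param targetsPerDrug length-2 integer range of targets per drug.
#' @param pathwaysPerDrug length-2 integer range of pathways per drug.
#' @param alpha,beta,gamma,noiseSd response model parameters (log-IC50 in
#'   natural-log micromolar).
#' @param exprBaseline,exprShift,exprSd expression model parameters
#'   (log-scale intensities).
#' @param seed integer seed.
#' @return a [SimConfig-class].
#' @export
simConfig <- function(nCellLines = 20L, nGenes = 100L, nTargets = 60L,
                      nDrugs = 10L, nPathways = 8L,
                      targetsPerDrug = c(2L, 6L), pathwaysPerDrug = c(1L, 3L),
                      alpha = 2, beta = 1.5, gamma = 0.7, noiseSd = 0.1,
                      exprBaseline = 6, exprShift = 2, exprSd = 0.5,
                      seed = 1L) {
  new("SimConfig", nCellLines = as.integer(nCellLines),
      nGenes = as.integer(nGenes), nTargets = as.integer(nTargets),
      nDrugs = as.integer(nDrugs), nPathways = as.integer(nPathways),
      targetsPerDrug = as.integer(targetsPerDrug),
      pathwaysPerDrug = as.integer(pathwaysPerDrug),
      alpha = alpha, beta = beta, gamma = gamma, noiseSd = noiseSd,
      exprBaseline = exprBaseline, exprShift = exprShift, exprSd = exprSd,
      seed = as.integer(seed))
}
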