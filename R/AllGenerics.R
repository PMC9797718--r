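#' @rdname FeatureSchema
#' @param object,x a SynergyNet object.
#' @export
setGeneric("genePanel", function(x) standardGeneric("genePanel"))

#' @rdname FeatureSchema
#' @export
setGeneric("targetUniverse", function(x) standardGeneric("targetUniverse"))

#' @rdname FeatureSchema
#' @export
setGeneric("featureDim", function(x) standardGeneric("featureDim"))

#' Feature matrix of a SampleSet (samples in rows)
#'
#' @param x a [SampleSet-class].
#' @return numeric matrix, one row per sample, columns in schema order.
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' Regression / classification labels of a SampleSet
#'
#' @param x a [SampleSet-class].
#' @param task `"regression"` (log-IC50) or `"classification"` (0/1).
#' @export
setGeneric("sampleLabels", function(x, task = "regression")
  standardGeneric("sampleLabels"))

#' IC50 (median-effect dose) of a fitted dose-response curve
#'
#' @param x a [MedianEffectFit-class].
#' @export
setGeneric("ic50", function(x) standardGeneric("ic50"))

#' Slope of a fitted median-effect curve
#'
#' @param x a [MedianEffectFit-class].
#' @export
setGeneric("slopeM", function(x) standardGeneric("slopeM"))

#' Per-epoch training loss history
#'
#' @param x a trained [DNNModel-class].
#' @return data.frame with columns `epoch` and `loss`.
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))

#' Number of trainable parameters
#'
#' @param x a [DNNModel-class] or [NetworkSpec-class].
#' @export
setGeneric("nParameters", function(x) standardGeneric("nParameters"))

## ---- accessors ----

#' @rdname FeatureSchema
#' @export
setMethod("genePanel", "FeatureSchema", function(x) x@genePanel)

#' @rdname FeatureSchema
#' @export
setMethod("targetUniverse", "FeatureSchema", function(x) x@targetUniverse)

#' @rdname FeatureSchema
#' @export
setMethod("featureDim", "FeatureSchema",
  function(x) length(x@genePanel) + length(x@targetUniverse))

#' @rdname FeatureSchema
#' @export
setMethod("show", "FeatureSchema", function(object) {
  cat("FeatureSchema:", length(object@genePanel), "panel genes +",
      length(object@targetUniverse), "targets =",
      featureDim(object), "features\n")
})

#' @rdname ic50
#' @export
setMethod("ic50", "MedianEffectFit", function(x) x@dm)

#' @rdname slopeM
#' @export
setMethod("slopeM", "MedianEffectFit", function(x) x@m)

setMethod("show", "MedianEffectFit", function(object) {
  cat(sprintf("MedianEffectFit: Dm (IC50) = %.6g, m = %.4g, r = %.4f (n = %d)\n",
              object@dm, object@m, object@r, object@n))
})

setMethod("show", "NetworkSpec", function(object) {
  cat("NetworkSpec:", object@inputDim, "->",
      paste(object@hiddenUnits, collapse = " -> "), "-> 1 (",
      if (object@task == "regression") "linear" else "sigmoid",
      "head ), dropout", object@dropoutRate, "\n")
})

setMethod("show", "DNNModel", function(object) {
  cat(if (object@trained) "Trained" else "Untrained", "DNNModel\n")
  show(object@spec)
  cat("  parameters:", nParameters(object), "\n")
  if (object@trained)
    cat("  final training loss:",
        signif(utils::tail(object@history$loss, 1), 6), "after",
        nrow(object@history), "epochs\n")
})

setMethod("show", "BaselineModel", function(object) {
  cat("BaselineModel:", object@family, "(", object@task, ")\n")
})

setMethod("show", "Standardizer", function(object) {
  cat("Standardizer over", length(object@center), "features;",
      sum(object@constant), "constant column(s)\n")
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0("SimConfig: %d cell lines x %d genes, %d targets, ",
                     "%d drugs, %d pathways (seed %d)\n"),
              object@nCellLines, object@nGenes, object@nTargets,
              object@nDrugs, object@nPathways, object@seed))
  cat(sprintf("  log-IC50 = %.3g - %.3g*cov - %.3g*max(cov-1,0) + N(0, %.3g^2)\n",
              object@alpha, object@beta, object@gamma, object@noiseSd))
})

#' @rdname trainingHistory
#' @export
setMethod("trainingHistory", "DNNModel", function(x) x@history)
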