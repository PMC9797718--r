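#' Regression performance scores
#'
#' Computes the mean square error `MSE = (1/m) sum (y_true - y_pre)^2`, its
#' square root RMSE, and `R2 = 1 - SSE/SST` where SST is the total sum of
#' squares around the mean of `yTrue`.
#'
#' @param yTrue,yPred numeric vectors of equal length (>= 2), finite.
#' @return named list with `mse`, `rmse`, `r2`.
#' @examples
#' regressionScores(c(0, 2), c(1, 1))  # mse 1, rmse 1, r2 0
#' @export
regressionScores <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred)) stop("length mismatch")
  if (length(yTrue) < 2L) stop("need at least 2 observations")
  if (!all(is.finite(yTrue)) || !all(is.finite(yPred)))
    stop("inputs must be finite")
  sst <- mean((yTrue - mean(yTrue))^2)
  if (sst == 0) stop("constant yTrue: R2 is undefined")
  mse <- mean((yTrue - yPred)^2)
  list(mse = mse, rmse = sqrt(mse), r2 = 1 - mse / sst)
}

#' Classification scores from a confusion table
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(FP+TN)`, accuracy
#' `(TP+TN)/total`, and the Matthews correlation coefficient. A metric
#' whose denominator is zero is reported as `NA` (flagged in
#' `$undefined`), never silently as 0.
#'
#' @param tp,tn,fp,fn non-negative integer counts.
#' @return named list with `sen`, `spe`, `acc`, `mcc` and `undefined`
#'   (character vector of metrics with zero denominators).
#' @examples
#' classificationScores(1, 1, 1, 1)  # all 0.5, mcc 0
#' @export
classificationScores <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (sum(counts) == 0) stop("empty confusion table")
  undef <- character()
  sen <- if (tp + fn > 0) tp / (tp + fn) else { undef <- c(undef, "sen"); NA_real_ }
  spe <- if (fp + tn > 0) tn / (fp + tn) else { undef <- c(undef, "spe"); NA_real_ }
  acc <- (tp + tn) / sum(counts)
  denom <- (tp + fn) * (tp + fp) * (tn + fn) * (tn + fp)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / sqrt(denom)
         else { undef <- c(undef, "mcc"); NA_real_ }
  list(sen = sen, spe = spe, acc = acc, mcc = mcc, undefined = undef)
}

#' Confusion counts from scores at a threshold
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores; predicted positive iff `score >= threshold`.
#' @param threshold decision threshold (default 0.5).
#' @return named list `tp`, `tn`, `fp`, `fn`.
#' @export
confusionCounts <- function(labels, scores, threshold = 0.5) {
  if (length(labels) != length(scores)) stop("length mismatch")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  pred <- as.integer(scores >= threshold)
  list(tp = sum(pred == 1 & labels == 1), tn = sum(pred == 0 & labels == 0),
       fp = sum(pred == 1 & labels == 0), fn = sum(pred == 0 & labels == 1))
}

#' ROC curve and AUC
#'
#' The ROC curve sweeps every distinct score as a threshold (predicted
#' positive iff score >= threshold); AUC is its trapezoidal integral,
#' which equals the rank statistic -- the probability that a random
#' positive outranks a random negative, ties counted one half.
#'
#' @param labels 0/1 vector with both classes present.
#' @param scores numeric scores, larger = more positive.
#' @return list with `auc` and `roc`, a data.frame of
#'   (`threshold`, `fpr`, `tpr`) points including the (0,0) and (1,1)
#'   endpoints.
#' @export
rocAuc <- function(labels, scores) {
  if (length(labels) != length(scores)) stop("length mismatch")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  ## cumulative counts at each distinct threshold (groups of tied scores)
  last <- !duplicated(sc, fromLast = TRUE)  # last index of each tie group
  tp <- cumsum(lab == 1)[last]
  fp <- cumsum(lab == 0)[last]
  tpr <- c(0, tp / npos, 1)
  fpr <- c(0, fp / nneg, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(auc = auc,
       roc = data.frame(threshold = c(Inf, sc[last], -Inf), fpr = fpr, tpr = tpr))
}

#' Combined metric report for a model on a test set
#'
#' @param yTrue true labels (log-IC50 or 0/1).
#' @param scores model scores.
#' @param task `"regression"` or `"classification"`.
#' @param threshold decision threshold for classification.
#' @return data.frame with columns `metric`, `value`.
#' @export
metricReport <- function(yTrue, scores, task = "regression", threshold = 0.5) {
  if (task == "regression") {
    s <- regressionScores(yTrue, scores)
    data.frame(metric = c("mse", "rmse", "r2"),
               value = c(s$mse, s$rmse, s$r2))
  } else {
    cc <- confusionCounts(yTrue, scores, threshold)
    s <- classificationScores(cc$tp, cc$tn, cc$fp, cc$fn)
    data.frame(metric = c("sen", "spe", "acc", "mcc", "auc"),
               value = c(s$sen, s$spe, s$acc, s$mcc,
                         rocAuc(yTrue, scores)$auc))
  }
}
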