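#' Restrict an expression matrix to a gene panel
#'
#' Rows are restricted to the panel genes present in the matrix, in panel
#' order. Duplicate rows for the same gene symbol (e.g. multiple probes
#' mapped to one symbol upstream) are collapsed by their arithmetic mean.
#' Panel genes absent from the matrix are dropped and reported in the
#' `"missing"` attribute.
#'
#' @param expr numeric matrix, genes in rows (rownames = symbols), cell
#'   lines in columns.
#' @param panel character vector of gene symbols defining the block layout.
#' @return the restricted matrix with attribute `missing` (character vector
#'   of panel genes not found).
#' @examples
#' m <- rbind(A = c(1, 2), G = c(2, 2), G2 = c(4, 4))
#' rownames(m)[3] <- "G"  # duplicate probe rows for G
#' selectGenePanel(m, c("G", "A"))
#' @export
selectGenePanel <- function(expr, panel) {
  panel <- as.character(panel)
  if (length(panel) == 0L) stop("gene panel is empty")
  if (is.null(rownames(expr))) stop("expression matrix must have gene rownames")
  expr <- as.matrix(expr)
  if (anyDuplicated(rownames(expr))) {
    expr <- rowsum(expr, group = rownames(expr)) /
      as.vector(table(rownames(expr))[sort(unique(rownames(expr)))])
  }
  found <- panel[panel %in% rownames(expr)]
  missing <- setdiff(panel, found)
  if (length(found) == 0L)
    stop("no panel gene found in the expression matrix; first missing: ",
         paste(utils::head(missing, 5), collapse = ", "))
  if (length(missing))
    warning(length(missing), " panel gene(s) absent from the matrix: ",
            paste(utils::head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ...")
  out <- expr[found, , drop = FALSE]
  attr(out, "missing") <- missing
  out
}

#' Encode a drug combination as a binary target fingerprint
#'
#' The target block of a combination is the element-wise OR (set union) of
#' the member drugs' binary target vectors over the schema's target
#' universe: 1 where any member drug hits the target, 0 elsewhere. A
#' singleton combination therefore equals the drug's own encoding.
#'
#' @param drugs character vector of member drug ids (a combination).
#' @param targetMap named list mapping drug id -> character vector of
#'   target ids (see [readDrugTargets()]).
#' @param schema a [FeatureSchema-class].
#' @return named binary numeric vector over `targetUniverse(schema)`.
#' @examples
#' sch <- FeatureSchema("G", c("t1", "t2", "t3", "t4"))
#' tm <- list(d1 = c("t1", "t3"), d2 = c("t3", "t4"))
#' encodeCombination(c("d1", "d2"), tm, sch)
#' @export
encodeCombination <- function(drugs, targetMap, schema) {
  drugs <- comboMembers(drugs)
  unknown <- setdiff(drugs, names(targetMap))
  if (length(unknown))
    stop("unknown drug(s) in combination: ", paste(unknown, collapse = ", "))
  universe <- targetUniverse(schema)
  hit <- unique(unlist(targetMap[drugs], use.names = FALSE))
  empty <- drugs[vapply(targetMap[drugs], length, 1L) == 0L]
  if (length(empty))
    warning("drug(s) with empty target set contribute zeros: ",
            paste(empty, collapse = ", "))
  v <- as.numeric(universe %in% hit)
  names(v) <- universe
  v
}

#' Assemble modeling samples from expression, targets and responses
#'
#' Builds one sample per response row: features are the cell line's
#' panel-restricted expression block concatenated with the drug's (or
#' combination's) binary target block. The regression label is the log of
#' the IC50 on the configured scale, and the classification label is 1 iff
#' the raw IC50 is at or below the threshold.
#'
#' @param expr numeric gene x cell-line matrix (will be panel-restricted).
#' @param targetMap named list drug -> targets.
#' @param responses data.frame with columns `drug_id`, `cell_line_id`,
#'   `ic50`, `unit`; `drug_id` may be a semicolon-joined combination id.
#' @param schema a [FeatureSchema-class].
#' @param labelScale `"ln_uM"` (natural log of IC50 in micromolar, the
#'   default), `"log10_nM"`, or `"raw"`.
#' @param classThreshold,thresholdUnit positive-class rule: label_class = 1
#'   iff IC50 <= `classThreshold` expressed in `thresholdUnit` (defaults
#'   10 nM).
#' @return a [SampleSet-class]. Rows rejected for nonpositive/missing IC50
#'   are counted in `metadata(x)$rejects`.
#' @export
assembleSamples <- function(expr, targetMap, responses, schema,
                            labelScale = c("ln_uM", "log10_nM", "raw"),
                            classThreshold = 10, thresholdUnit = "nM") {
  labelScale <- match.arg(labelScale)
  req <- c("drug_id", "cell_line_id", "ic50", "unit")
  if (!all(req %in% names(responses)))
    stop("responses must have columns ", paste(req, collapse = ", "))
  expr <- selectGenePanel(expr, genePanel(schema))
  panel <- rownames(expr)

  unknown_cl <- setdiff(unique(responses$cell_line_id), colnames(expr))
  if (length(unknown_cl))
    stop("response rows reference unknown cell line(s): ",
         paste(utils::head(unknown_cl, 5), collapse = ", "))

  ok <- is.finite(responses$ic50) & responses$ic50 > 0
  nrej <- sum(!ok)
  if (nrej) {
    warning(nrej, " response row(s) with nonpositive or missing IC50 skipped")
    responses <- responses[ok, , drop = FALSE]
  }
  if (nrow(responses) == 0L) stop("no valid response rows")

  ic50_uM <- convertConc(responses$ic50, responses$unit, "uM")
  thr_uM <- convertConc(classThreshold, thresholdUnit, "uM")
  label_reg <- switch(labelScale,
    ln_uM = log(ic50_uM),
    log10_nM = log10(convertConc(responses$ic50, responses$unit, "nM")),
    raw = responses$ic50)
  label_cls <- as.integer(ic50_uM <= thr_uM)

  combos <- strsplit(as.character(responses$drug_id), ";", fixed = TRUE)
  tmat <- vapply(combos, encodeCombination, numeric(length(targetUniverse(schema))),
                 targetMap = targetMap, schema = schema)
  features <- rbind(expr[, responses$cell_line_id, drop = FALSE], tmat)
  rownames(features) <- c(panel, targetUniverse(schema))
  colnames(features) <- sprintf("s%04d", seq_len(ncol(features)))

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = features),
    rowData = S4Vectors::DataFrame(
      block = rep(c("gene", "target"), c(length(panel),
                                         length(targetUniverse(schema))))),
    colData = S4Vectors::DataFrame(
      cell_line = responses$cell_line_id,
      combination_id = vapply(combos, comboId, ""),
      drugs = vapply(combos, function(d) paste(comboMembers(d), collapse = ";"), ""),
      ic50_uM = ic50_uM,
      label_regression = label_reg,
      label_class = label_cls,
      row.names = colnames(features)))
  S4Vectors::metadata(se) <- list(schema = schema, labelScale = labelScale,
                                  standardized = FALSE, rejects = nrej,
                                  panelMissing = attr(expr, "missing"))
  new("SampleSet", se)
}

#' @rdname featureMatrix
#' @export
setMethod("featureMatrix", "SampleSet", function(x)
  t(SummarizedExperiment::assay(x, "features")))

#' @rdname sampleLabels
#' @export
setMethod("sampleLabels", "SampleSet", function(x, task = "regression") {
  cd <- SummarizedExperiment::colData(x)
  if (identical(task, "classification")) cd$label_class else cd$label_regression
})

setMethod("show", "SampleSet", function(object) {
  cat("SampleSet:", ncol(object), "samples x", nrow(object), "features (",
      sum(SummarizedExperiment::rowData(object)$block == "gene"), "gene +",
      sum(SummarizedExperiment::rowData(object)$block == "target"), "target )\n")
  cat("  label scale:", S4Vectors::metadata(object)$labelScale,
      "| standardized:", S4Vectors::metadata(object)$standardized, "\n")
})

#' Fit a feature standardizer on a training split
#'
#' Learns per-column mean and population standard deviation (zero-centered
#' processing and normalized square deviation) on the training samples
#' only. Constant columns are flagged and transformed to exactly 0. All
#' columns, including the binary target block, are standardized.
#'
#' @param x a [SampleSet-class] or samples-in-rows numeric matrix.
#' @return a [Standardizer-class].
#' @export
fitStandardizer <- function(x) {
  m <- if (is(x, "SampleSet")) featureMatrix(x) else as.matrix(x)
  if (nrow(m) < 2L) stop("need at least 2 training samples")
  center <- colMeans(m)
  scale <- sqrt(colMeans(sweep(m, 2L, center)^2))  # population sd
  constant <- scale == 0
  new("Standardizer", center = center, scale = scale, constant = constant)
}

#' Apply (or invert) a fitted standardizer
#'
#' Test data are always transformed with training-split statistics only.
#' Constant training columns map to 0; `inverseStandardize` restores them
#' to the training mean.
#'
#' @param std a fitted [Standardizer-class].
#' @param x a [SampleSet-class] or samples-in-rows matrix.
#' @return object of the same type as `x` with transformed features.
#' @export
applyStandardizer <- function(std, x) {
  if (!is(std, "Standardizer")) stop("standardizer is not fitted")
  .std_transform(std, x, inverse = FALSE)
}

#' @rdname applyStandardizer
#' @export
inverseStandardize <- function(std, x) .std_transform(std, x, inverse = TRUE)

.std_transform <- function(std, x, inverse) {
  m <- if (is(x, "SampleSet")) featureMatrix(x) else as.matrix(x)
  if (ncol(m) != length(std@center))
    stop("feature dimension mismatch: standardizer has ", length(std@center),
         ", data has ", ncol(m))
  s <- ifelse(std@constant, 1, std@scale)
  z <- if (inverse) sweep(sweep(m, 2L, s, "*"), 2L, std@center, "+")
       else sweep(sweep(m, 2L, std@center), 2L, s, "/")
  if (!inverse && any(std@constant)) z[, std@constant] <- 0
  if (is(x, "SampleSet")) {
    SummarizedExperiment::assay(x, "features") <- t(z)
    S4Vectors::metadata(x)$standardized <- !inverse
    x
  } else z
}

#' Split samples into training and test sets
#'
#' The training size is `round-half-up(trainFraction * n)`; the remainder
#' goes to test. Membership is a seeded uniform draw, deterministic for a
#' fixed seed; the two parts are disjoint and exhaustive.
#'
#' @param x a [SampleSet-class] (or anything with `length`/columns via `n`).
#' @param trainFraction fraction in (0, 1); default 0.8.
#' @param seed integer seed.
#' @return list with elements `train` and `test` (subsets of `x`), plus
#'   `trainIndex`.
#' @examples
#' splitSizes(201405, 0.8)  # 161124 train, 40281 test
#' @export
splitDataset <- function(x, trainFraction = 0.8, seed = 1L) {
  n <- ncol(x)
  sizes <- splitSizes(n, trainFraction)
  idx <- .with_seed(seed, sample.int(n, sizes[["train"]]))
  list(train = x[, idx], test = x[, setdiff(seq_len(n), idx)],
       trainIndex = sort(idx))
}

#' @rdname splitDataset
#' @param n total number of samples.
#' @return `splitSizes()` returns a named vector `c(train =, test =)`.
#' @export
splitSizes <- function(n, trainFraction = 0.8) {
  .check_scalar(trainFraction, "trainFraction")
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must be strictly between 0 and 1")
  if (n < 2L) stop("need at least 2 samples to split")
  ntrain <- floor(trainFraction * n + 0.5)  # round half up
  c(train = ntrain, test = n - ntrain)
}
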