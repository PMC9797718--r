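.delim_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read a gene x cell-line expression matrix
#'
#' TSV (default) or CSV by file extension; first column holds gene
#' symbols, the header the cell-line ids. Duplicate gene rows are
#' collapsed by arithmetic mean. Missing values are an error unless
#' `imputeMean = TRUE`, which fills them with the column (cell-line)
#' mean.
#'
#' @param path input file.
#' @param imputeMean impute missing cells with the column mean.
#' @return numeric matrix with gene rownames.
#' @export
readExpressionMatrix <- function(path, imputeMean = FALSE) {
  df <- utils::read.delim(path, sep = .delim_for(path), header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("expression file is empty or has no cell-line columns: ", path)
  genes <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1L], is.numeric, TRUE))[1L]
    badrow <- which(is.na(suppressWarnings(as.numeric(df[[bad + 1L]]))))[1L]
    stop("non-numeric expression value at row ", badrow, ", column ",
         colnames(df)[bad + 1L])
  }
  rownames(m) <- genes
  if (anyNA(m)) {
    if (!imputeMean) {
      idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
      stop("missing value at gene ", genes[idx[1L]], ", cell line ",
           colnames(m)[idx[2L]], " (set imputeMean = TRUE to impute)")
    }
    for (j in seq_len(ncol(m))) {
      nas <- is.na(m[, j])
      if (any(nas)) m[nas, j] <- mean(m[, j], na.rm = TRUE)
    }
  }
  if (anyDuplicated(rownames(m)))
    m <- selectGenePanel(m, unique(rownames(m)))
  message("expression matrix: ", nrow(m), " genes x ", ncol(m), " cell lines")
  m
}

#' @rdname readExpressionMatrix
#' @param expr numeric matrix with gene rownames.
#' @export
writeExpressionMatrix <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = .delim_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a drug-target map
#'
#' Two-column TSV (`drug_id`, `target_id`), one pair per row. Targets are
#' de-duplicated per drug; the distinct target ids form the reported
#' universe.
#'
#' @param path input file.
#' @return named list drug -> character vector of targets, with attribute
#'   `universe`.
#' @export
readDrugTargets <- function(path) {
  df <- utils::read.delim(path, sep = .delim_for(path), header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0L) stop("empty drug-target file: ", path)
  if (ncol(df) < 2L) stop("drug-target file needs two columns")
  blank <- !nzchar(trimws(df[[1L]])) | !nzchar(trimws(df[[2L]]))
  if (any(blank))
    stop("blank drug or target id at line ", which(blank)[1L] + 1L)
  tm <- lapply(split(df[[2L]], df[[1L]]), unique)
  universe <- sort(unique(df[[2L]]), method = "radix")
  message("drug-target map: ", length(tm), " drugs, ",
          length(universe), " distinct targets")
  attr(tm, "universe") <- universe
  tm
}

#' @rdname readDrugTargets
#' @param targetMap named list drug -> targets.
#' @export
writeDrugTargets <- function(targetMap, path) {
  df <- data.frame(
    drug_id = rep(names(targetMap), lengths(targetMap)),
    target_id = unlist(targetMap, use.names = FALSE))
  utils::write.table(df, path, sep = .delim_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a monotherapy response table
#'
#' Columns `drug_id`, `cell_line_id`, `ic50`, `unit`. Rows with
#' nonpositive or missing IC50 are rejected and counted (attribute
#' `rejected`). Duplicate (drug, cell line) pairs are resolved by the
#' geometric mean of their IC50s with a warning (IC50s are log-scale
#' quantities).
#'
#' @param path input file.
#' @return data.frame of validated records.
#' @export
readResponseTable <- function(path) {
  df <- utils::read.delim(path, sep = .delim_for(path), header = TRUE,
                          stringsAsFactors = FALSE)
  req <- c("drug_id", "cell_line_id", "ic50", "unit")
  if (!all(req %in% names(df)))
    stop("response table must have columns ", paste(req, collapse = ", "))
  df$ic50 <- suppressWarnings(as.numeric(df$ic50))
  bad <- !is.finite(df$ic50) | df$ic50 <= 0
  if (any(bad)) {
    warning(sum(bad), " response row(s) with nonpositive/missing IC50 rejected")
    df <- df[!bad, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no valid response rows in ", path)
  for (u in unique(df$unit))
    message("responses in ", u, ": ", sum(df$unit == u))
  key <- paste(df$drug_id, df$cell_line_id, df$unit, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate (drug, cell line) pair(s) ",
            "resolved by geometric mean")
    gm <- exp(tapply(log(df$ic50), key, mean))
    df <- df[!duplicated(key), , drop = FALSE]
    df$ic50 <- as.numeric(gm[paste(df$drug_id, df$cell_line_id, df$unit,
                                   sep = "\r")])
  }
  rej <- sum(bad)
  attr(df, "rejected") <- rej
  rownames(df) <- NULL
  df
}

#' @rdname readResponseTable
#' @param responses data.frame with the response columns.
#' @export
writeResponseTable <- function(responses, path) {
  utils::write.table(responses[, c("drug_id", "cell_line_id", "ic50", "unit")],
                     path, sep = .delim_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' Reading is delegated to [fgsea::gmtPathways()]. Writing emits the
#' standard layout: set name, description, then one member per field.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
readGMT <- function(path) fgsea::gmtPathways(path)

#' @rdname readGMT
#' @param sets named list of character vectors.
#' @param description description field (recycled).
#' @export
writeGMT <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a dose-response plate table
#'
#' Long-format TSV with columns `combination_id`, `ratio_label`,
#' `drug_id`, `dose`, `unit`, `viability_fraction`, `replicate`. `dose`
#' is the total well concentration (repeated across the member-drug rows
#' of a combination well); zero-dose rows are untreated controls.
#'
#' @param path input file.
#' @return data.frame ready for [analyzePlates()].
#' @export
readPlateTable <- function(path) {
  df <- utils::read.delim(path, sep = .delim_for(path), header = TRUE,
                          stringsAsFactors = FALSE)
  req <- c("combination_id", "ratio_label", "drug_id", "dose", "unit",
           "viability_fraction", "replicate")
  if (!all(req %in% names(df)))
    stop("plate table must have columns ", paste(req, collapse = ", "))
  if (any(!is.finite(df$dose) | df$dose < 0)) stop("doses must be >= 0")
  df
}

#' @rdname readPlateTable
#' @param plate plate data.frame.
#' @export
writePlateTable <- function(plate, path) {
  utils::write.table(plate, path, sep = .delim_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Assemble, validate and snapshot a pipeline run configuration
#'
#' A run configuration collects the input paths and modeling options of a
#' full pipeline run. It is validated eagerly and is fully serializable;
#' [writeRunConfig()] snapshots it as JSON next to a run's outputs so any
#' run can be reproduced from its snapshot.
#'
#' @param expression,targets,responses input file paths (optional; NA
#'   allowed for simulated runs).
#' @param labelScale `"ln_uM"`, `"log10_nM"` or `"raw"`.
#' @param classThreshold,thresholdUnit positive-class IC50 rule.
#' @param model `"dnn"`, `"knn"`, `"rf"`, `"svm"` or `"gbm"`.
#' @param task `"regression"` or `"classification"`.
#' @param trainFraction split fraction in (0, 1).
#' @param seed integer seed.
#' @param outputDir directory for run outputs.
#' @return validated list of class `"synergynet_run_config"`.
#' @export
runConfig <- function(expression = NA, targets = NA, responses = NA,
                      labelScale = "ln_uM", classThreshold = 10,
                      thresholdUnit = "nM", model = "dnn",
                      task = "regression", trainFraction = 0.8, seed = 1L,
                      outputDir = ".") {
  stopifnot(labelScale %in% c("ln_uM", "log10_nM", "raw"),
            model %in% c("dnn", "knn", "rf", "svm", "gbm"),
            task %in% c("regression", "classification"))
  .check_scalar(classThreshold, "classThreshold", lower = 1e-12)
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must be in (0, 1)")
  convertConc(1, thresholdUnit)  # unit check
  structure(list(expression = expression, targets = targets,
                 responses = responses, labelScale = labelScale,
                 classThreshold = classThreshold,
                 thresholdUnit = thresholdUnit, model = model, task = task,
                 trainFraction = trainFraction, seed = as.integer(seed),
                 outputDir = outputDir),
            class = "synergynet_run_config")
}

#' @rdname runConfig
#' @param config a run configuration.
#' @param path JSON file path.
#' @export
writeRunConfig <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname runConfig
#' @export
readRunConfig <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(runConfig, x[!vapply(x, is.null, TRUE)])
}

#' Write a metric report as CSV and/or JSON
#'
#' @param report data.frame from [metricReport()].
#' @param path output path; `.json` writes JSON, anything else CSV.
#' @param model,task annotations added as columns.
#' @export
writeMetricReport <- function(report, path, model = "dnn",
                              task = "regression") {
  out <- cbind(model = model, task = task, report)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(out, path, dataframe = "rows", digits = NA)
  else utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
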