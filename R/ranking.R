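#' Enumerate candidate drug combinations from a pool
#'
#' Generates every subset of the pool with size in `[minSize, maxSize]`,
#' each exactly once, in canonical order (by size, then lexicographically
#' by canonical id). With `minSize = 2` and `maxSize = n` this yields
#' `2^n - n - 1` combinations; a 7-drug pool gives 120. Singletons can be
#' appended so the ranking universe also contains the individual drugs
#' (127 entries for 7 drugs).
#'
#' @param pool character vector of drug ids.
#' @param minSize,maxSize subset size bounds, `1 <= minSize <= maxSize <=
#'   length(pool)`.
#' @param includeSingletons append the single drugs after the combinations
#'   (ignored if `minSize == 1` already includes them).
#' @return list of character vectors (sorted members).
#' @examples
#' length(enumerateCombinations(letters[1:7], 2, 7))  # 120
#' @export
enumerateCombinations <- function(pool, minSize = 2L, maxSize = length(pool),
                                  includeSingletons = FALSE) {
  pool <- unique(as.character(pool))
  if (length(pool) == 0L) stop("empty drug pool")
  if (minSize < 1L || minSize > maxSize || maxSize > length(pool))
    stop("need 1 <= minSize <= maxSize <= |pool|")
  sorted <- sort(pool, method = "radix")
  combos <- list()
  for (k in seq(minSize, maxSize)) {
    sets <- utils::combn(sorted, k, simplify = FALSE)
    sets <- sets[order(vapply(sets, paste, "", collapse = ";"), method = "radix")]
    combos <- c(combos, sets)
  }
  if (includeSingletons && minSize > 1L)
    combos <- c(combos, as.list(sorted))
  combos
}

#' Rank drug combinations in a cell line by predicted pseudo-IC50
#'
#' Builds one prediction sample per combination -- the cell line's
#' standardized expression block concatenated with the union target
#' fingerprint -- scores all of them with the trained model, and sorts
#' ascending (lower pseudo-IC50 = more potent). The pseudo-IC50 is the raw
#' model score used only to rank; it is never converted back to a
#' concentration. Ties break by canonical combination id.
#'
#' @param model a trained [DNNModel-class] or [BaselineModel-class].
#' @param expr expression matrix containing `cellLine`'s column (gene rows).
#' @param cellLine cell line identifier (a column of `expr`).
#' @param combos list of drug-id vectors, e.g. from
#'   [enumerateCombinations()].
#' @param targetMap named list drug -> targets.
#' @param schema the [FeatureSchema-class] the model was trained under.
#' @param standardizer the fitted [Standardizer-class] from the training
#'   split.
#' @return data.frame with columns `cell_line`, `rank`, `combination_id`,
#'   `member_drugs`, `n_drugs`, `pseudo_ic50`, sorted ascending with
#'   consecutive ranks from 1.
#' @export
rankCombinations <- function(model, expr, cellLine, combos, targetMap,
                             schema, standardizer) {
  if (!length(combos)) stop("no combinations to rank")
  all_drugs <- unique(unlist(combos))
  unknown <- setdiff(all_drugs, names(targetMap))
  if (length(unknown))
    stop("unknown drug(s) in combinations: ", paste(unknown, collapse = ", "))
  expr <- selectGenePanel(expr, genePanel(schema))
  if (!cellLine %in% colnames(expr))
    stop("cell line ", cellLine, " not in the expression matrix")

  tmat <- vapply(combos, encodeCombination,
                 numeric(length(targetUniverse(schema))),
                 targetMap = targetMap, schema = schema)
  feats <- t(rbind(matrix(expr[, cellLine], nrow = nrow(expr),
                          ncol = length(combos)), tmat))
  colnames(feats) <- c(rownames(expr), targetUniverse(schema))
  z <- applyStandardizer(standardizer, feats)
  scores <- predict(model, z)

  ids <- vapply(combos, comboId, "")
  ord <- order(scores, ids, method = "radix")
  data.frame(cell_line = cellLine,
             rank = seq_along(combos),
             combination_id = ids[ord],
             member_drugs = ids[ord],
             n_drugs = lengths(combos)[ord],
             pseudo_ic50 = scores[ord],
             row.names = NULL)
}

#' Write a ranking table to CSV
#'
#' @param ranking data.frame from [rankCombinations()].
#' @param path output file.
#' @export
writeRankingTable <- function(ranking, path) {
  utils::write.csv(ranking, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
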