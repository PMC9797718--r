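#' Build a gene-set collection over a background universe
#'
#' Sets are restricted to the universe; members outside it are dropped and
#' sets left empty after restriction are removed with a warning.
#'
#' @param sets named list of character vectors (e.g. from [readGMT()]).
#' @param universe character vector of background genes.
#' @return list with elements `sets` (restricted) and `universe`.
#' @export
geneSetCollection <- function(sets, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("gene sets must be named")
  restricted <- lapply(sets, function(s) intersect(unique(s), universe))
  empty <- lengths(restricted) == 0L
  if (any(empty)) {
    warning(sum(empty), " gene set(s) empty after universe restriction, dropped: ",
            paste(utils::head(names(sets)[empty], 5), collapse = ", "))
    restricted <- restricted[!empty]
  }
  if (!length(restricted)) stop("no gene set survives universe restriction")
  list(sets = restricted, universe = universe)
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, the one-sided hypergeometric tail probability of
#' drawing at least the observed overlap when sampling `|query|` genes
#' without replacement from the universe. A set is significant iff
#' `p < alpha` (default 0.01). No multiple-testing correction is applied
#' by default; `adjust = "BH"` adds Benjamini-Hochberg adjusted p-values
#' and applies the cutoff to those instead.
#'
#' @param query character vector of query genes (e.g. the union of a
#'   combination's targets intersected with the cell line's feature
#'   genes). Genes outside the universe are dropped with a warning.
#' @param collection a [geneSetCollection()].
#' @param alpha significance cutoff (default 0.01).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame sorted ascending by p with columns `set`,
#'   `universe_size`, `set_size`, `query_size`, `overlap`, `p`,
#'   (`p_adjust`,) `significant`.
#' @export
overrepresentation <- function(query, collection, alpha = 0.01,
                               adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!length(query)) stop("empty query")
  query <- unique(as.character(query))
  outside <- setdiff(query, collection$universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped: ",
            paste(utils::head(outside, 5), collapse = ", "))
    query <- setdiff(query, outside)
  }
  if (!length(query)) stop("no query gene left after universe restriction")

  N <- length(collection$universe)
  n <- length(query)
  rows <- lapply(names(collection$sets), function(nm) {
    K <- length(collection$sets[[nm]])
    k <- length(intersect(query, collection$sets[[nm]]))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, universe_size = N, set_size = K, query_size = n,
               overlap = k, p = p)
  })
  out <- do.call(rbind, rows)
  if (adjust == "BH") {
    out$p_adjust <- stats::p.adjust(out$p, method = "BH")
    out$significant <- out$p_adjust < alpha
  } else {
    out$significant <- out$p < alpha
  }
  out[order(out$p, out$set), , drop = FALSE]
}

#' Query gene set of a drug combination
#'
#' The union of the member drugs' targets, optionally intersected with a
#' cell line's feature genes (the panel), ready for
#' [overrepresentation()].
#'
#' @param drugs character vector of member drug ids.
#' @param targetMap named list drug -> targets.
#' @param featureGenes optional character vector to intersect with.
#' @return character vector of query genes.
#' @export
combinationQueryGenes <- function(drugs, targetMap, featureGenes = NULL) {
  drugs <- comboMembers(drugs)
  unknown <- setdiff(drugs, names(targetMap))
  if (length(unknown))
    stop("unknown drug(s): ", paste(unknown, collapse = ", "))
  q <- unique(unlist(targetMap[drugs], use.names = FALSE))
  if (!is.null(featureGenes)) q <- intersect(q, featureGenes)
  q
}
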