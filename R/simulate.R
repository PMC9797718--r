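#' Generate a synthetic drug-response world with known ground truth
#'
#' Builds a seeded toy world in which synergy is complementary pathway
#' coverage. Genes and targets are partitioned over pathways; each cell
#' line activates each pathway independently with probability 1/2;
#' pathway-member genes are elevated by `exprShift` in cell lines where
#' the pathway is active (plus Gaussian noise). Each drug draws its
#' targets from 1-3 pathways, so a combination's union fingerprint covers
#' a known set of pathways and the true log-IC50 is
#' `alpha - beta * nCov - gamma * max(nCov - 1, 0)`, with `nCov` the
#' number of distinct ACTIVE pathways covered in that cell line. The whole
#' world is deterministic given the config.
#'
#' @param config a [simConfig()].
#' @return list with `config`, `expression` (genes x cell lines),
#'   `targetMap`, `schema`, `activity` (cell lines x pathways, 0/1),
#'   `genePathway`, `targetPathway`, and `pathwayGeneSets`.
#' @export
generateWorld <- function(config) {
  validObject(config)
  .with_seed(config@seed, {
    cells <- sprintf("CL%02d", seq_len(config@nCellLines))
    genes <- sprintf("g%03d", seq_len(config@nGenes))
    targets <- sprintf("t%03d", seq_len(config@nTargets))
    drugs <- sprintf("drug%02d", seq_len(config@nDrugs))
    pws <- sprintf("pw%d", seq_len(config@nPathways))

    ## round-robin base assignment keeps every pathway non-empty
    genePathway <- stats::setNames(
      sample(rep_len(seq_len(config@nPathways), config@nGenes)), genes)
    targetPathway <- stats::setNames(
      sample(rep_len(seq_len(config@nPathways), config@nTargets)), targets)

    activity <- matrix(stats::rbinom(config@nCellLines * config@nPathways, 1L, 0.5),
                       config@nCellLines, config@nPathways,
                       dimnames = list(cells, pws))

    shift <- config@exprShift * activity[, genePathway, drop = FALSE]  # cells x genes
    expr <- config@exprBaseline + t(shift) +
      matrix(stats::rnorm(config@nGenes * config@nCellLines, 0, config@exprSd),
             config@nGenes, config@nCellLines)
    dimnames(expr) <- list(genes, cells)

    targetMap <- lapply(seq_len(config@nDrugs), function(i) {
      npw <- sample(seq(config@pathwaysPerDrug[1], config@pathwaysPerDrug[2]), 1L)
      pw <- sample.int(config@nPathways, min(npw, config@nPathways))
      pool <- names(targetPathway)[targetPathway %in% pw]
      nt <- sample(seq(config@targetsPerDrug[1], config@targetsPerDrug[2]), 1L)
      sample(pool, min(nt, length(pool)))
    })
    names(targetMap) <- drugs

    list(config = config,
         expression = expr,
         targetMap = targetMap,
         schema = FeatureSchema(genes, targets),
         activity = activity,
         genePathway = genePathway,
         targetPathway = targetPathway,
         pathwayGeneSets = split(names(genePathway), pws[genePathway]))
  })
}

#' Ground-truth log-IC50 of a drug set in a cell line
#'
#' Deterministic given the world: `alpha - beta * nCov - gamma *
#' max(nCov - 1, 0)` with `nCov` the number of distinct active pathways
#' covered by the union of the member drugs' targets. A sham combination
#' (a drug with itself) has the single drug's truth. Values are natural
#' logs of micromolar concentrations.
#'
#' @param world a [generateWorld()] result.
#' @param cellLine cell line id.
#' @param drugs character vector of member drug ids.
#' @return numeric scalar.
#' @export
trueLogIC50 <- function(world, cellLine, drugs) {
  drugs <- comboMembers(drugs)
  unknown <- setdiff(drugs, names(world$targetMap))
  if (length(unknown)) stop("unknown drug(s): ", paste(unknown, collapse = ", "))
  if (!cellLine %in% rownames(world$activity))
    stop("unknown cell line: ", cellLine)
  targets <- unique(unlist(world$targetMap[drugs], use.names = FALSE))
  covered <- unique(world$targetPathway[targets])
  ncov <- sum(world$activity[cellLine, covered])
  cfg <- world$config
  cfg@alpha - cfg@beta * ncov - cfg@gamma * max(ncov - 1, 0)
}

#' Generate monotherapy responses and combination ground truth
#'
#' The observed table contains one row per (cell line, single drug) with
#' `ic50 = exp(truth + noise)` micromolar -- only monotherapy rows, as in
#' a screening resource. The combination truth table retains the
#' noise-free true log-IC50 of every requested combination for
#' evaluation.
#'
#' @param world a [generateWorld()] result.
#' @param combos list of drug-id vectors; default all combinations of 2-4
#'   drugs from the pool.
#' @param seed seed for the label noise (defaults to the world seed + 1).
#' @return list with `monotherapy` (data.frame `drug_id`, `cell_line_id`,
#'   `ic50`, `unit`) and `combinationTruth` (data.frame `cell_line_id`,
#'   `combination_id`, `n_drugs`, `true_log_ic50`).
#' @export
generateResponses <- function(world, combos = NULL, seed = NULL) {
  cfg <- world$config
  if (is.null(seed)) seed <- cfg@seed + 1L
  if (is.null(combos))
    combos <- enumerateCombinations(names(world$targetMap), 2L,
                                    min(4L, cfg@nDrugs))
  cells <- rownames(world$activity)
  drugs <- names(world$targetMap)

  mono <- expand.grid(drug_id = drugs, cell_line_id = cells,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  truth <- mapply(function(d, c) trueLogIC50(world, c, d),
                  mono$drug_id, mono$cell_line_id)
  noise <- .with_seed(seed, stats::rnorm(nrow(mono), 0, cfg@noiseSd))
  mono$ic50 <- exp(truth + noise)
  mono$unit <- "uM"

  ct <- expand.grid(i = seq_along(combos), cell_line_id = cells,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  comboTruth <- data.frame(
    cell_line_id = ct$cell_line_id,
    combination_id = vapply(combos[ct$i], comboId, ""),
    n_drugs = lengths(combos)[ct$i],
    true_log_ic50 = mapply(function(i, c) trueLogIC50(world, c, combos[[i]]),
                           ct$i, ct$cell_line_id))
  list(monotherapy = mono, combinationTruth = comboTruth)
}

#' Generate dose-response plates from the synthetic world
#'
#' Viability curves follow the median-effect equation with
#' `Dm = exp(true log-IC50)` micromolar and a configurable shared slope:
#' an 8-point two-fold dilution series per (combination, ratio setting),
#' bracketing Dm, plus a zero-dose control well. Multiplicative
#' (log-normal) noise can be applied to the viability readout; with
#' `noiseSd = 0` the series is exact, so [fitMedianEffect()] round-trips
#' Dm. Monotherapy plates for each member drug are included so
#' [analyzePlates()] can compute combination indices.
#'
#' @param world a [generateWorld()] result.
#' @param cellLine cell line id.
#' @param combos list of drug-id vectors.
#' @param slope median-effect slope m shared by all curves (default 1.5).
#' @param noiseSd sd of the log-normal viability noise (default 0).
#' @param nDoses dilution points per series (default 8).
#' @param replicates wells per dose (default 3).
#' @param seed seed for the plate noise (defaults to world seed + 2).
#' @return long-format plate data.frame as consumed by [analyzePlates()]
#'   and written/read by [writePlateTable()]/[readPlateTable()].
#' @export
generatePlates <- function(world, cellLine, combos, slope = 1.5,
                           noiseSd = 0, nDoses = 8L, replicates = 3L,
                           seed = NULL) {
  if (is.null(seed)) seed <- world$config@seed + 2L
  all_series <- list()
  for (combo in combos) {
    members <- comboMembers(combo)
    unknown <- setdiff(members, names(world$targetMap))
    if (length(unknown))
      stop("unknown drug(s) in combination: ", paste(unknown, collapse = ", "))
    schemes <- if (length(members) == 1L) list(I = 1L)
               else ratioScheme(length(members))
    for (lbl in names(schemes)) {
      all_series[[length(all_series) + 1L]] <-
        list(id = comboId(members), label = lbl, members = members)
    }
  }
  .with_seed(seed, {
    rows <- lapply(all_series, function(s) {
      dm <- exp(trueLogIC50(world, cellLine, s$members))
      ## two-fold dilution series containing Dm itself (so fa = 0.5 exactly
      ## at one well when noise-free)
      doses <- dm * 2^(seq_len(nDoses) - ceiling(nDoses / 2))
      fa <- doses^slope / (doses^slope + dm^slope)
      grid <- expand.grid(dose = c(0, doses), replicate = seq_len(replicates),
                          KEEP.OUT.ATTRS = FALSE)
      via <- ifelse(grid$dose == 0, 1,
                    1 - fa[match(grid$dose, doses)])
      if (noiseSd > 0)
        via <- pmin(via * exp(stats::rnorm(length(via), 0, noiseSd)), 1.2)
      do.call(rbind, lapply(s$members, function(d)
        data.frame(combination_id = s$id, ratio_label = s$label, drug_id = d,
                   dose = grid$dose, unit = "uM",
                   viability_fraction = via, replicate = grid$replicate)))
    })
    do.call(rbind, c(rows, make.row.names = FALSE))
  })
}

#' Write the synthetic world in the package's exchange formats
#'
#' Emits exactly the TSV/GMT files the readers consume: the expression
#' matrix, the drug-target map, the monotherapy response table, and the
#' pathway gene sets, so a round trip through the I/O layer exercises the
#' full path.
#'
#' @param world a [generateWorld()] result.
#' @param responses a [generateResponses()] result (or NULL to skip).
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
writeWorld <- function(world, responses = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             targets = file.path(dir, "drug_targets.tsv"),
             pathways = file.path(dir, "pathways.gmt"))
  writeExpressionMatrix(world$expression, paths[["expression"]])
  writeDrugTargets(world$targetMap, paths[["targets"]])
  writeGMT(world$pathwayGeneSets, paths[["pathways"]])
  if (!is.null(responses)) {
    paths[["responses"]] <- file.path(dir, "responses.tsv")
    writeResponseTable(responses$monotherapy, paths[["responses"]])
  }
  invisible(paths)
}
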