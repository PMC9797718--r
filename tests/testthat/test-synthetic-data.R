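test_that("world generation honors dimensions, seeding and contracts", {
  cfg <- simConfig(nCellLines = 10L, nGenes = 50L, nTargets = 30L,
                   nDrugs = 8L, nPathways = 5L, seed = 3L)
  w <- generateWorld(cfg)
  expect_equal(dim(w$expression), c(50L, 10L))
  expect_length(w$targetMap, 8L)
  expect_true(all(lengths(w$targetMap) >= 1L))
  expect_equal(featureDim(w$schema), 80L)
  expect_equal(dim(w$activity), c(10L, 5L))
  expect_true(all(w$activity %in% 0:1))

  ## bit-identical regeneration from the same config
  w2 <- generateWorld(cfg)
  expect_identical(w$expression, w2$expression)
  expect_identical(w$targetMap, w2$targetMap)
  expect_identical(w$activity, w2$activity)

  ## a different seed gives a different world
  w3 <- generateWorld(simConfig(nCellLines = 10L, nGenes = 50L,
                                nTargets = 30L, nDrugs = 8L,
                                nPathways = 5L, seed = 4L))
  expect_false(identical(w$expression, w3$expression))

  expect_error(generateWorld(simConfig(nTargets = 3L,
                                       targetsPerDrug = c(2L, 6L))),
               "nTargets")
})

test_that("pathway-member genes are elevated where the pathway is active", {
  tw <- tiny_world()
  w <- tw$world
  cfg <- w$config
  diffs <- vapply(seq_len(cfg@nPathways), function(p) {
    genes <- names(w$genePathway)[w$genePathway == p]
    act <- w$activity[, p] == 1
    if (!any(act) || all(act)) return(NA_real_)
    mean(w$expression[genes, act]) - mean(w$expression[genes, !act])
  }, numeric(1))
  expect_equal(mean(diffs, na.rm = TRUE), cfg@exprShift, tolerance = 0.5)
})

test_that("response truths follow the coverage formula and set semantics", {
  tw <- tiny_world()
  w <- tw$world
  cfg <- w$config
  ## independent evaluation of the truth formula
  for (cl in rownames(w$activity)[1:3]) {
    for (d in names(w$targetMap)[1:4]) {
      pws <- unique(w$targetPathway[w$targetMap[[d]]])
      ncov <- sum(w$activity[cl, pws])
      expected <- cfg@alpha - cfg@beta * ncov - cfg@gamma * max(ncov - 1, 0)
      expect_equal(trueLogIC50(w, cl, d), expected)
    }
  }

  ## sham combination equals the single drug
  expect_equal(trueLogIC50(w, "CL01", c("drug01", "drug01")),
               trueLogIC50(w, "CL01", "drug01"))

  ## adding drugs never raises the truth; covering a new active pathway
  ## strictly lowers it
  for (cl in rownames(w$activity)) {
    t1 <- trueLogIC50(w, cl, "drug01")
    t12 <- trueLogIC50(w, cl, c("drug01", "drug02"))
    expect_lte(t12, t1 + 1e-12)
    pw1 <- unique(w$targetPathway[w$targetMap[["drug01"]]])
    pw2 <- unique(w$targetPathway[w$targetMap[["drug02"]]])
    new_active <- setdiff(pw2, pw1)
    if (length(new_active) && any(w$activity[cl, new_active] == 1))
      expect_lt(t12, t1)
  }

  ## noise-free labels equal the formula exactly
  w0 <- generateWorld(tiny_config(noiseSd = 0))
  r0 <- generateResponses(w0)
  m <- r0$monotherapy
  for (i in sample(nrow(m), 10)) {
    expect_equal(log(m$ic50[i]),
                 trueLogIC50(w0, m$cell_line_id[i], m$drug_id[i]),
                 tolerance = 1e-12)
  }

  ## monotherapy table exposes only single-drug rows
  expect_false(any(grepl(";", m$drug_id)))
  expect_true(all(grepl(";", r0$combinationTruth$combination_id[
    r0$combinationTruth$n_drugs > 1])))
})

test_that("generated plates follow the median-effect equation and reseed", {
  tw <- tiny_world()
  w <- tw$world
  d <- names(w$targetMap)[1]
  plate <- generatePlates(w, "CL02", list(d), noiseSd = 0, replicates = 2L)
  dm <- exp(trueLogIC50(w, "CL02", d))
  at_dm <- plate[abs(plate$dose - dm) < 1e-12 & plate$replicate == 1, ]
  expect_equal(1 - at_dm$viability_fraction[1], 0.5, tolerance = 1e-12)

  fit <- analyzePlates(plate)
  expect_equal(fit$ic50, dm, tolerance = 1e-9)
  expect_equal(fit$m, 1.5, tolerance = 1e-9)

  noisy1 <- generatePlates(w, "CL02", list(d), noiseSd = 0.05, seed = 5L)
  noisy2 <- generatePlates(w, "CL02", list(d), noiseSd = 0.05, seed = 5L)
  expect_identical(noisy1, noisy2)
  expect_error(generatePlates(w, "CL02", list("ghost")), "unknown drug")
})

test_that("synthetic synergy shows in the combination index", {
  tw <- tiny_world()
  w <- tw$world
  ## pick a combination covering >= 2 distinct active pathways in some cell
  pool <- names(w$targetMap)
  found <- NULL
  for (cl in rownames(w$activity)) {
    for (combo in enumerateCombinations(pool, 2, 2)) {
      pws <- unique(w$targetPathway[unlist(w$targetMap[combo])])
      if (sum(w$activity[cl, pws]) >= 2 &&
          all(sapply(combo, function(d) {
            p1 <- unique(w$targetPathway[w$targetMap[[d]]])
            sum(w$activity[cl, p1]) >= 1
          }))) { found <- list(cl = cl, combo = combo); break }
    }
    if (!is.null(found)) break
  }
  skip_if(is.null(found), "tiny world has no doubly-covered combination")

  plate <- generatePlates(w, found$cl,
                          c(as.list(found$combo), list(found$combo)),
                          noiseSd = 0)
  res <- analyzePlates(plate)
  ci <- res$ci[res$combination_id == comboId(found$combo)]
  expect_true(all(ci < 0.9))   # synergy bonus makes the combo super-additive

  ## sham combination under mild noise stays within 1 +/- 0.05
  d <- found$combo[1]
  sham_plate <- generatePlates(w, found$cl, list(d), noiseSd = 0.02,
                               replicates = 3L, seed = 9L)
  sfit <- analyzePlates(sham_plate)
  single <- fitMedianEffect(
    tapply(sham_plate$dose[sham_plate$dose > 0],
           sham_plate$dose[sham_plate$dose > 0], unique),
    tapply(1 - sham_plate$viability_fraction[sham_plate$dose > 0],
           sham_plate$dose[sham_plate$dose > 0], mean))
  res_sham <- combinationIndex(list(single, single),
                               unique(sham_plate$dose[sham_plate$dose > 0]),
                               tapply(1 - sham_plate$viability_fraction[sham_plate$dose > 0],
                                      sham_plate$dose[sham_plate$dose > 0], mean),
                               c(1, 1), 0.5)
  expect_equal(res_sham$ci, 1, tolerance = 0.05)
})

test_that("the world writes and re-reads through the exchange formats", {
  tw <- tiny_world()
  dir <- withr::local_tempdir()
  paths <- writeWorld(tw$world, tw$responses, dir)
  expr <- suppressMessages(readExpressionMatrix(paths[["expression"]]))
  expect_equal(expr, tw$world$expression, tolerance = 1e-12)
  tm <- suppressMessages(readDrugTargets(paths[["targets"]]))
  expect_equal(lapply(tm, sort),
               lapply(tw$world$targetMap[names(tm)], sort))
  resp <- suppressMessages(readResponseTable(paths[["responses"]]))
  expect_equal(nrow(resp), nrow(tw$responses$monotherapy))
  sets <- readGMT(paths[["pathways"]])
  expect_equal(lapply(sets, sort),
               lapply(tw$world$pathwayGeneSets[names(sets)], sort))
})
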