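test_that("median-effect fitting recovers exact curves", {
  s <- me_series(dm = 2, m = 1, doses = c(0.25, 0.5, 1, 2, 4, 8))
  fit <- fitMedianEffect(s$doses, s$fa)
  expect_equal(ic50(fit), 2, tolerance = 1e-9)
  expect_equal(slopeM(fit), 1, tolerance = 1e-9)
  expect_equal(abs(fit@r), 1, tolerance = 1e-9)

  ## fa at D = Dm is 0.5 by construction: the fit's IC50 is that dose
  expect_equal(s$fa[4], 0.5)

  ## parameter recovery across a grid of (Dm, m), to 1e-9
  for (dm in c(0.3, 5, 120)) for (m in c(0.6, 1, 2.5)) {
    g <- me_series(dm, m, dm * 2^seq(-3, 3))
    f <- fitMedianEffect(g$doses, g$fa)
    expect_equal(ic50(f), dm, tolerance = 1e-9 * dm)
    expect_equal(slopeM(f), m, tolerance = 1e-9)
  }

  expect_error(fitMedianEffect(c(1, 2), c(0.3, 0.6)), "3 dose points")
  expect_error(fitMedianEffect(c(0, 1, 2), c(0.1, 0.3, 0.6)), "positive")
})

test_that("noisy dose-response fits stay near truth", {
  ## 8-point series bracketing the IC50 by two doublings either side,
  ## 5% multiplicative noise on fraction affected
  s <- me_series(dm = 10, m = 1.5, doses = 10 * 2^seq(-2, 2, length.out = 8))
  for (seed in 1:5) {
    set.seed(seed)
    fa_noisy <- pmin(pmax(s$fa * exp(rnorm(8, 0, 0.05)), 1e-3), 0.999)
    fit <- fitMedianEffect(s$doses, fa_noisy)
    expect_lt(abs(ic50(fit) - 10) / 10, 0.15)
  }
})

test_that("ratio schemes reproduce the tested concentration grids", {
  two <- ratioScheme(2)
  expect_equal(two, list(I = c(1L, 1L), II = c(2L, 1L), III = c(1L, 2L)))
  five <- ratioScheme(5)
  expect_length(five, 6L)
  expect_equal(five$VI, c(1L, 1L, 1L, 1L, 2L))
  for (k in 2:5) {
    sch <- ratioScheme(k)
    expect_length(sch, k + 1L)
    expect_equal(sch[[1]], rep(1L, k))
    for (j in 2:(k + 1L)) {
      expect_equal(sum(sch[[j]] == 2L), 1L)   # exactly one doubled part
      expect_equal(which(sch[[j]] == 2L), j - 1L)
    }
  }
  expect_error(ratioScheme(6), "2 to 5")
  expect_error(ratioScheme(1), "2 to 5")
})

test_that("sham combinations give CI = 1 exactly", {
  set.seed(17)
  for (i in 1:25) {
    dm <- runif(1, 0.1, 50); m <- runif(1, 0.5, 3)
    k <- sample(2:4, 1)
    ratio <- sample(1:3, k, replace = TRUE)
    fa_level <- runif(1, 0.1, 0.9)
    doses <- dm * 2^seq(-3, 3)
    s <- me_series(dm, m, doses)
    fits <- replicate(k, fitMedianEffect(s$doses, s$fa))
    res <- combinationIndex(fits, s$doses, s$fa, ratio, fa_level)
    expect_equal(res$ci, 1, tolerance = 1e-9)
    expect_equal(res$category, "additive")
  }
})

test_that("combination index evaluates the dose-sum directly", {
  ## singles with Dm = 4 (m = 1); combo pseudo-agent with Dm = 2, ratio 1:1:
  ## at fa = 0.5, Dc = 2 so each drug contributes 1 = Dx/4, CI = 0.5
  single <- fitMedianEffect(c(1, 2, 4, 8, 16), me_series(4, 1, c(1, 2, 4, 8, 16))$fa)
  combo <- me_series(2, 1, c(0.5, 1, 2, 4, 8))
  res <- combinationIndex(list(single, single), combo$doses, combo$fa,
                          c(1, 1), 0.5)
  expect_equal(res$ci, 0.5, tolerance = 1e-9)
  expect_equal(res$category, "synergy")
  expect_error(combinationIndex(list(single), combo$doses, combo$fa,
                                c(1, 1), 0.5), "per ratio part")
  expect_error(combinationIndex(list(single, single), combo$doses, combo$fa,
                                c(1, 1), 1.2), "effect level")
})

test_that("CI category boundaries are closed/open as stated", {
  eps <- 1e-12
  expect_equal(ciCategory(0.3 - eps), "strong-synergy")
  expect_equal(ciCategory(0.3), "synergy")
  expect_equal(ciCategory(0.9 - eps), "synergy")
  expect_equal(ciCategory(0.9), "additive")
  expect_equal(ciCategory(1.0), "additive")
  expect_equal(ciCategory(1.1), "additive")
  expect_equal(ciCategory(1.1 + 1e-9), "antagonism")
  expect_equal(ciCategory(1.2), "antagonism")
})

test_that("best IC50 takes the minimum across ratio settings", {
  row <- bestIC50(c(90.43, 31.37, 30.88, 42.94))
  expect_equal(row$value, 30.88)
  expect_equal(row$label, "III")
  expect_equal(bestIC50(c(177, 52, 139, 2152, 167))$value, 52)
  expect_equal(bestIC50(5)$value, 5)

  set.seed(23)
  for (i in 1:10) {
    v <- runif(sample(2:6, 1), 1, 1000)
    perm <- sample(v)
    expect_equal(bestIC50(perm)$value, bestIC50(v)$value)
    expect_true(all(bestIC50(v)$value <= v))
  }
  expect_error(bestIC50(numeric(0)), "empty")
  expect_error(bestIC50(c(3, -1)), "positive")
})

test_that("relative potency reports percent and fold change", {
  p <- relativePotency(115.5, 207.6)
  expect_equal(p$percent, 55.6)
  expect_equal(relativePotency(115.5, 774.2)$percent, 14.9)
  eq <- relativePotency(3, 3)
  expect_equal(eq$percent, 100.0)
  expect_equal(eq$fold, 1)
  expect_error(relativePotency(0, 1))
})

test_that("plate analysis fits series, averages replicates, computes CI", {
  tw <- tiny_world()
  w <- tw$world
  drugs <- names(w$targetMap)[1:2]
  plate <- generatePlates(w, "CL01", list(drugs[1], drugs[2], drugs),
                          slope = 1.3, noiseSd = 0)
  res <- analyzePlates(plate)
  singles <- res[res$combination_id %in% drugs, ]
  for (d in drugs)
    expect_equal(singles$ic50[singles$combination_id == d],
                 exp(trueLogIC50(w, "CL01", d)), tolerance = 1e-9)
  combo_rows <- res[res$combination_id == comboId(drugs), ]
  expect_equal(nrow(combo_rows), 3L)            # ratios I, II, III
  expect_true(all(is.finite(combo_rows$ci)))

  ## mixed units are refused
  plate2 <- plate
  plate2$unit[1] <- "nM"
  expect_error(analyzePlates(plate2), "mixed dose units")
})
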