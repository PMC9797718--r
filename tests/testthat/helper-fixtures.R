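## Shared tiny fixtures, built in code. The small world keeps most tests in
## milliseconds; the reference world is only built where a test needs it.

tiny_config <- function(...) {
  simConfig(nCellLines = 6L, nGenes = 30L, nTargets = 20L, nDrugs = 6L,
            nPathways = 4L, targetsPerDrug = c(2L, 4L), seed = 7L, ...)
}

.tiny_world_cache <- new.env(parent = emptyenv())

tiny_world <- function() {
  if (is.null(.tiny_world_cache$world)) {
    .tiny_world_cache$world <- generateWorld(tiny_config())
    .tiny_world_cache$responses <- generateResponses(.tiny_world_cache$world)
  }
  list(world = .tiny_world_cache$world,
       responses = .tiny_world_cache$responses)
}

## A 2-gene / 4-target schema with a hand-written target map.
toy_schema <- function() FeatureSchema(c("gA", "gB"), paste0("t", 1:4))

toy_target_map <- function()
  list(d1 = c("t1", "t3"), d2 = c("t3", "t4"), d3 = character(0))

toy_expression <- function() {
  m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3, ncol = 2,
              dimnames = list(c("gA", "gB", "gC"), c("c1", "c2")))
  m
}

## Exact median-effect series: fa = D^m / (D^m + Dm^m).
me_series <- function(dm, m, doses) {
  list(doses = doses, fa = doses^m / (doses^m + dm^m))
}

## Independent AUC oracle: pairwise rank statistic with half credit for ties.
pairwise_auc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

## Independent hypergeometric tail oracle by direct summation over the
## overlap support.
hyper_tail <- function(k, setSize, universeSize, querySize) {
  jmax <- min(setSize, querySize)
  if (k > jmax) return(0)
  sum(vapply(k:jmax, function(j)
    choose(setSize, j) * choose(universeSize - setSize, querySize - j),
    numeric(1))) / choose(universeSize, querySize)
}
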