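# Shared fixtures. Heavy end-to-end objects are computed lazily, once per
# test run, and reused across test files.

# Reduced cohort: same planted structure as the defaults, smaller matrix so
# unit tests stay fast.
smallConfig <- function(seed = 1L, ...) {
  SimulationConfig(nGenes = 500L, nSamples = 140L, kTrue = 6L,
                   immuneFactorIndex = 4L, immuneGeneCount = 80L,
                   stromalGeneCount = 60L, seed = seed, ...)
}

stromaTemplateOf <- function(cohort, minOverlap = 5L) {
  NTPTemplate("activated-stroma", cohort$truth$stromalGenes,
              minOverlap = minOverlap)
}

.fixtureCache <- new.env(parent = emptyenv())

memo <- function(key, value) {
  if (!exists(key, envir = .fixtureCache)) assign(key, force(value), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

# Default-size cohort plus a full discovery run (used by the pipeline-level
# acceptance checks and reused for the transfer test).
defaultRun <- function(seed = 101L) {
  memo(paste0("defaultRun", seed), {
    cohort <- simulateCohort(SimulationConfig(seed = seed))
    res <- runImmuneClassification(
      cohort$expr, cohort$signatures[["IMMUNE_TRUE"]],
      stromaTemplateOf(cohort), seed = seed, maxIter = 300L, tol = 1e-5,
      nPerm = 500L)
    list(cohort = cohort, res = res)
  })
}

smallRun <- function(seed = 7L) {
  memo(paste0("smallRun", seed), {
    cohort <- simulateCohort(smallConfig(seed = seed))
    res <- runImmuneClassification(
      cohort$expr, cohort$signatures[["IMMUNE_TRUE"]],
      stromaTemplateOf(cohort), k = 6L, topN = 60L, nRuns = 20L, seed = seed,
      maxIter = 300L, tol = 1e-5, nPerm = 300L)
    list(cohort = cohort, res = res)
  })
}

randomExprMatrix <- function(nGenes, nSamples, seed) {
  set.seed(seed)
  m <- matrix(rexp(nGenes * nSamples, 1 / 10), nGenes, nSamples,
              dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                              sprintf("s%03d", seq_len(nSamples))))
  ExpressionMatrix(m)
}
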