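#' Run the full immune classification cascade on one cohort
#'
#' Convenience wrapper chaining the discovery stages: immune enrichment
#' scoring, MAD gene prefilter, rank-`k` NMF microdissection, dominant-factor
#' assignment, immune-factor selection, exemplar-gene extraction, k = 2
#' consensus clustering into immune / non-immune classes, MDS random-forest
#' label refinement, the stromal NTP split into immune-activated /
#' immune-suppressed subclasses, and the 150-gene differential-expression
#' transfer classifier.
#'
#' @param expr an [ExpressionMatrix-class] (linear scale).
#' @param immuneSignature a [GeneSet-class] immune signature.
#' @param stromaTemplate an [NTPTemplate-class] activated-stroma template.
#' @param k microdissection rank (default 10).
#' @param topN exemplar / classifier gene count (default 150).
#' @param nRuns consensus restarts (default 30).
#' @param seed master seed; stage seeds are derived from it.
#' @param madTop genes kept by the MAD prefilter before the rank-`k` run.
#' @param nPerm NTP resampling permutations.
#' @param maxIter,tol NMF iteration controls.
#' @param refine apply the MDS random-forest refinement (default TRUE).
#' @return list with `immuneScores`, `nmf`, `assignment`, `factorReport`,
#'   `exemplars`, `twoLevel` ([ClassLabels-class]), `threeLevel`
#'   ([ClassLabels-class]), `classifier` (data.frame).
#' @export
runImmuneClassification <- function(expr, immuneSignature, stromaTemplate,
                                    k = 10L, topN = 150L, nRuns = 30L,
                                    seed = 1L, madTop = 5000L, nPerm = 1000L,
                                    maxIter = 2000L, tol = 1e-6,
                                    refine = TRUE) {
  seed <- as.integer(seed)
  immuneScores <- immuneEnrichmentScore(expr, immuneSignature)
  filtered <- madFilter(expr, madTop)
  fit <- nmfFactorize(filtered, k = k, seed = seed, maxIter = maxIter,
                      tol = tol)
  assignment <- assignFactors(fit)
  report <- selectImmuneFactor(assignment, immuneScores)
  exem <- exemplarScores(basisMatrix(fit), report$chosenFactor, topN = topN)
  twoLevel <- discoverClasses(expr, exem$selected, immuneScores,
                              nRuns = nRuns, seed = seed + 1L,
                              maxIter = maxIter, tol = tol)
  if (refine) {
    sub <- alignGenes(expr, exem$selected)
    twoLevel <- refineLabels(sub, twoLevel, seed = seed + 2L)
  }
  threeLevel <- splitSubclasses(expr, twoLevel, stromaTemplate,
                                nPerm = nPerm, seed = seed + 3L)
  classifier <- classifierGenes(expr, twoLevel, n = topN)
  list(immuneScores = immuneScores, nmf = fit, assignment = assignment,
       factorReport = report, exemplars = exem, twoLevel = twoLevel,
       threeLevel = threeLevel, classifier = classifier)
}
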