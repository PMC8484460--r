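#' Signal-to-noise marker ranking for one class
#'
#' Ranks genes by the signal-to-noise ratio
#' `SNR = (mu_in - mu_out) / (sigma_in + sigma_out)` on log2(x+1) values,
#' descending. Each class standard deviation is floored at
#' `max(0.2 |mu|, 0.2)` (the GenePattern convention) so near-constant genes
#' cannot dominate.
#'
#' @param expr an [ExpressionMatrix-class].
#' @param labels a [ClassLabels-class] or named character vector.
#' @param targetClass label value defining the "in" group.
#' @return named numeric vector of SNR values sorted descending.
#' @export
markerRanking <- function(expr, labels, targetClass) {
  lab <- if (is(labels, "ClassLabels")) sampleLabels(labels) else labels
  lab <- lab[sampleIds(expr)]
  if (any(is.na(lab))) stop("labels missing for some samples")
  isIn <- lab == targetClass
  if (sum(isIn) < 3L || sum(!isIn) < 3L)
    stop("target class and complement each need >= 3 samples")
  lx <- logExpr(expr)
  snr <- .snr(lx[, isIn, drop = FALSE], lx[, !isIn, drop = FALSE])
  sort(snr, decreasing = TRUE)
}

.snr <- function(xin, xout) {
  muIn <- rowMeans(xin); muOut <- rowMeans(xout)
  sdFix <- function(x, mu) {
    n <- ncol(x)
    s <- sqrt(pmax(rowSums((x - mu)^2) / (n - 1), 0))
    pmax(s, 0.2 * abs(mu), 0.2)
  }
  (muIn - muOut) / (sdFix(xin, muIn) + sdFix(xout, muOut))
}

# Weighted Kolmogorov-Smirnov enrichment of `markers` in a descending SNR
# ranking (classic subclass-mapping / GSEA statistic: hits weighted by
# |SNR|, misses uniform; signed maximum deviation).
.ksEnrichment <- function(markers, ranking) {
  hit <- names(ranking) %in% markers
  if (!any(hit)) return(0)
  w <- abs(ranking)
  wHit <- ifelse(hit, w, 0)
  sw <- sum(wHit)
  pHit <- if (sw > 0) cumsum(wHit) / sw else cumsum(hit) / sum(hit)
  pMiss <- cumsum(!hit) / max(sum(!hit), 1L)
  dev <- pHit - pMiss
  dev[which.max(abs(dev))]
}

#' Subclass mapping between two labeled cohorts
#'
#' Tests, for every pair of classes (a in cohort A, b in cohort B), whether
#' the top `nMarker` markers of `a` are enriched at the top of B's
#' b-vs-rest SNR ranking and reciprocally. Each direction gets a
#' permutation p-value by shuffling the respective cohort's labels
#' (`nPerm` times); the two one-sided p-values are combined by Fisher's
#' method (chi-square with 4 df) and Bonferroni-corrected across the tested
#' cells. Cohorts are first restricted to their shared gene space
#' (at least 200 genes required). Classes with fewer than 3 samples are
#' excluded (NA cells).
#'
#' @param exprA,exprB [ExpressionMatrix-class] cohorts.
#' @param labelsA,labelsB [ClassLabels-class] or named character vectors.
#' @param nMarker markers per class (default 50).
#' @param nPerm label permutations per direction (default 200; must be >= 1).
#' @param seed RNG seed.
#' @return list with `p` (classesA x classesB Fisher-combined p),
#'   `bonferroni`, `pAB`, `pBA` (per-direction), `esAB`, `esBA` (observed
#'   statistics), `nPerm`, `nMarker`.
#' @export
submapCompare <- function(exprA, labelsA, exprB, labelsB, nMarker = 50L,
                          nPerm = 200L, seed = 1L) {
  if (nPerm < 1L) stop("nPerm must be >= 1")
  labA <- if (is(labelsA, "ClassLabels")) sampleLabels(labelsA) else labelsA
  labB <- if (is(labelsB, "ClassLabels")) sampleLabels(labelsB) else labelsB
  shared <- intersect(geneIds(exprA), geneIds(exprB))
  if (length(shared) < 200L)
    stop("shared gene space has ", length(shared), " genes; >= 200 required")
  A <- logExpr(alignGenes(exprA, shared))[, names(labA), drop = FALSE]
  B <- logExpr(alignGenes(exprB, shared))[, names(labB), drop = FALSE]
  clA <- sort(unique(labA)); clB <- sort(unique(labB))
  okA <- clA[vapply(clA, function(cl) sum(labA == cl) >= 3L &&
                      sum(labA != cl) >= 3L, logical(1))]
  okB <- clB[vapply(clB, function(cl) sum(labB == cl) >= 3L &&
                      sum(labB != cl) >= 3L, logical(1))]
  if (!length(okA) || !length(okB)) stop("no class with >= 3 samples on each side")

  rankingsFor <- function(M, lab, classes) {
    lapply(stats::setNames(classes, classes), function(cl) {
      snr <- .snr(M[, lab == cl, drop = FALSE], M[, lab != cl, drop = FALSE])
      sort(snr, decreasing = TRUE)
    })
  }
  rankA <- rankingsFor(A, labA, okA)
  rankB <- rankingsFor(B, labB, okB)
  markersA <- lapply(rankA, function(r) names(r)[seq_len(min(nMarker, length(r)))])
  markersB <- lapply(rankB, function(r) names(r)[seq_len(min(nMarker, length(r)))])

  obsES <- function(markers, rankings)
    vapply(rankings, function(r) .ksEnrichment(markers, r), numeric(1))
  esAB <- t(vapply(markersA, function(mk) obsES(mk, rankB),
                   numeric(length(okB))))   # a x b: markers of a in B
  esBA <- vapply(markersB, function(mk) obsES(mk, rankA),
                 numeric(length(okA)))      # a x b after this orientation
  esBA <- matrix(esBA, nrow = length(okA),
                 dimnames = list(okA, okB))
  dimnames(esAB) <- list(okA, okB)

  nullCount <- function(M, lab, classes, markerList, observed, permSeed) {
    # observed: |markerList| x |classes| matrix; returns counts of
    # perm ES >= observed
    cnt <- matrix(0L, nrow(observed), ncol(observed))
    withSeed(permSeed, {
      for (b in seq_len(nPerm)) {
        pl <- sample(lab)
        rk <- rankingsFor(M, pl, classes)
        es <- t(vapply(markerList, function(mk) obsES(mk, rk),
                       numeric(length(classes))))
        cnt <- cnt + (es >= observed)
      }
    })
    cnt
  }
  # direction A -> B permutes B's labels; B -> A permutes A's labels
  cntAB <- nullCount(B, labB, okB, markersA, esAB, seed)
  cntBA <- nullCount(A, labA, okA,
                     markerList = markersB,
                     observed = t(esBA), permSeed = seed + 1L)
  pAB <- (1 + cntAB) / (1 + nPerm)
  pBA <- t((1 + cntBA) / (1 + nPerm))
  dimnames(pAB) <- dimnames(pBA) <- list(okA, okB)
  fisher <- stats::pchisq(-2 * (log(pAB) + log(pBA)), df = 4,
                          lower.tail = FALSE)
  fisher <- pmax(fisher, 1 / (1 + nPerm)^2)   # keep strictly in (0, 1]
  cells <- length(okA) * length(okB)
  list(p = fisher, bonferroni = pmin(fisher * cells, 1),
       pAB = pAB, pBA = pBA, esAB = esAB, esBA = esBA,
       nPerm = nPerm, nMarker = nMarker)
}
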