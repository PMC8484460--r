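#' Select the immune factor from a factorization
#'
#' Groups samples by dominant factor, runs a Kruskal-Wallis omnibus test of
#' the immune enrichment score across groups, and a one-sided one-vs-rest
#' Wilcoxon test per factor (BH-adjusted). The chosen factor is the argmax
#' of group medians; a flag is raised when its adjusted one-vs-rest p-value
#' is not significant. Groups with fewer than 3 samples are excluded from
#' testing (and from the argmax) with a warning.
#'
#' @param assignment data.frame from [assignFactors()].
#' @param immuneScores named per-sample immune score vector
#'   (see [immuneEnrichmentScore()]).
#' @return list with `chosenFactor`, `groupMedians`, `kruskalP`,
#'   `pairwise` (data.frame: factor, n, median, p, pAdj) and
#'   `notSignificant` flag.
#' @export
selectImmuneFactor <- function(assignment, immuneScores) {
  stopifnot(all(c("sample_id", "factor") %in% colnames(assignment)))
  if (!all(assignment$sample_id %in% names(immuneScores)))
    stop("every sample needs an immune score")
  score <- immuneScores[assignment$sample_id]
  fac <- assignment$factor
  sizes <- table(fac)
  tested <- as.integer(names(sizes)[sizes >= 3])
  if (length(tested) < 2L)
    stop("need at least two factor groups with >= 3 samples")
  if (length(tested) < length(sizes))
    warning("factor group(s) with < 3 samples excluded from testing: ",
            paste(setdiff(names(sizes), as.character(tested)), collapse = ", "))
  keep <- fac %in% tested
  kw <- stats::kruskal.test(score[keep], factor(fac[keep]))
  med <- vapply(tested, function(f) stats::median(score[fac == f]), numeric(1))
  pw <- vapply(tested, function(f) {
    stats::wilcox.test(score[fac == f], score[keep & fac != f],
                       alternative = "greater", exact = FALSE)$p.value
  }, numeric(1))
  pAdj <- stats::p.adjust(pw, method = "BH")
  chosen <- tested[which.max(med)]
  list(chosenFactor = chosen,
       groupMedians = stats::setNames(med, paste0("F", tested)),
       kruskalP = kw$p.value,
       pairwise = data.frame(factor = tested, n = as.integer(sizes[as.character(tested)]),
                             median = med, p = pw, pAdj = pAdj,
                             row.names = NULL),
       notSignificant = pAdj[which.max(med)] >= 0.05)
}

#' Rank genes by immune-factor specificity and pick exemplars
#'
#' Scores every gene by the difference between its loading on the immune
#' factor and its maximum loading on any other factor,
#' `s_g = W[g, imm] - max_{j != imm} W[g, j]`, sorts descending (ties at the
#' cutoff broken by gene name), and selects the top `topN` exemplar genes.
#'
#' @param W genes x k loading matrix (e.g. [basisMatrix()] of an
#'   [NMFResult-class]).
#' @param immuneFactor column index of the immune factor.
#' @param topN number of exemplar genes to select (default 150).
#' @return list with `scores` (named, sorted descending), `ranked` (gene
#'   names in rank order) and `selected` (top `topN` genes).
#' @export
exemplarScores <- function(W, immuneFactor, topN = 150L) {
  W <- as.matrix(W)
  if (ncol(W) < 2L) stop("exemplar scoring needs k >= 2 factors")
  if (immuneFactor < 1L || immuneFactor > ncol(W))
    stop("immune factor index out of range")
  if (is.null(rownames(W))) stop("W must carry gene names")
  other <- W[, -immuneFactor, drop = FALSE]
  s <- W[, immuneFactor] - apply(other, 1, max)
  ord <- order(-s, rownames(W))   # stable: score desc, then gene name
  ranked <- rownames(W)[ord]
  list(scores = stats::setNames(s[ord], ranked), ranked = ranked,
       selected = utils::head(ranked, min(topN, length(ranked))))
}

# Consensus k=2 on a gene subset, polarity by median immune score.
# The gene panel is one-sided (high in the immune class), so the submatrix is
# log2-transformed, gene-wise standardized and "posneg"-doubled (positive and
# negative parts stacked as separate nonnegative rows) before factorization;
# this anchors one factor on marker-high and one on marker-low samples, which
# raw-intensity k=2 NMF cannot do when both classes share one profile shape.
.twoClassConsensus <- function(expr, genes, immuneScores, nRuns, baseSeed,
                               maxIter, tol, provenance) {
  sub <- alignGenes(expr, genes, minCoverage = 0.5)
  z <- .rowStandardize(logExpr(sub))
  doubled <- rbind(pmax(z, 0), pmax(-z, 0))
  rownames(doubled) <- c(paste0(rownames(z), ".pos"),
                         paste0(rownames(z), ".neg"))
  cons <- consensusNMF(doubled, k = 2L, nRuns = nRuns, baseSeed = baseSeed,
                       maxIter = maxIter, tol = tol)
  cl <- cons$labels
  med <- vapply(1:2, function(g) stats::median(immuneScores[names(cl)[cl == g]]),
                numeric(1))
  if (any(is.na(med))) stop("a consensus cluster is empty")
  if (med[1] == med[2])
    stop("cluster immune-score medians tie; increase nRuns")
  immuneCluster <- which.max(med)
  lab <- ifelse(cl == immuneCluster, "immune", "non-immune")
  list(labels = ClassLabels(names(cl), lab, provenance = provenance),
       consensus = cons)
}

#' Discover immune / non-immune classes
#'
#' Runs k = 2 NMF consensus clustering on the exemplar-gene submatrix; the
#' cluster with the higher median immune enrichment score is labeled
#' `"immune"`.
#'
#' @param expr an [ExpressionMatrix-class] (full cohort).
#' @param exemplars character vector of exemplar genes.
#' @param immuneScores named per-sample immune score vector.
#' @param nRuns consensus restarts (default 30).
#' @param seed base seed for the restarts.
#' @param maxIter,tol forwarded to [nmfFactorize()].
#' @return A two-level [ClassLabels-class] with the consensus result in
#'   attribute `"consensus"`.
#' @export
discoverClasses <- function(expr, exemplars, immuneScores, nRuns = 30L,
                            seed = 1L, maxIter = 2000L, tol = 1e-6) {
  if (ncol(expr) < 20L) stop("class discovery needs >= 20 samples")
  res <- .twoClassConsensus(expr, exemplars, immuneScores, nRuns, seed,
                            maxIter, tol, "discovery")
  out <- res$labels
  attr(out, "consensus") <- res$consensus
  out
}

#' Refine class labels with the MDS random-forest method
#'
#' Fits a random forest (default 500 trees) on the exemplar-gene expression
#' against the preliminary labels, converts the forest's co-leaf proximity
#' into a distance, embeds samples by classical MDS in 2 dimensions, and
#' reassigns each sample to the majority label among its `kNeighbors`
#' nearest embedded neighbors, iterating the relabeling to a fixed point (at
#' most `maxRounds` rounds). If either class has fewer than `minClassSize`
#' samples, refinement is skipped with a warning.
#'
#' @param exprSub [ExpressionMatrix-class] restricted to the exemplar genes.
#' @param prelim two-level [ClassLabels-class].
#' @param seed RNG seed for the forest.
#' @param nTrees,kNeighbors,maxRounds,minClassSize tuning knobs.
#' @return A refined [ClassLabels-class]; the number of flipped labels is in
#'   attribute `"flips"`.
#' @export
refineLabels <- function(exprSub, prelim, seed = 1L, nTrees = 500L,
                         kNeighbors = 15L, maxRounds = 10L,
                         minClassSize = 10L) {
  stopifnot(is(prelim, "ClassLabels"))
  lab <- sampleLabels(prelim)
  if (!all(sort(unique(lab)) %in% .twoLevel))
    stop("refinement expects two-level immune/non-immune labels")
  if (min(table(lab)) < minClassSize) {
    warning("a class has fewer than ", minClassSize,
            " samples; refinement skipped")
    out <- ClassLabels(sampleIds(prelim), lab, provenance = "refined")
    attr(out, "flips") <- 0L
    return(out)
  }
  X <- t(logExpr(exprSub))[names(lab), , drop = FALSE]
  rf <- withSeed(seed, randomForest::randomForest(
    x = X, y = factor(lab), ntree = nTrees, proximity = TRUE))
  d <- 1 - rf$proximity
  mds <- stats::cmdscale(stats::as.dist(d), k = 2)
  dd <- as.matrix(stats::dist(mds))
  diag(dd) <- Inf
  nn <- apply(dd, 1, function(row) order(row)[seq_len(kNeighbors)])
  cur <- lab
  for (round in seq_len(maxRounds)) {
    nxt <- vapply(seq_along(cur), function(i) majorityLabel(cur[nn[, i]]),
                  character(1))
    names(nxt) <- names(cur)
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  out <- ClassLabels(names(cur), unname(cur), provenance = "refined")
  attr(out, "flips") <- sum(cur != lab)
  out
}

#' Derive the transfer classifier genes by differential expression
#'
#' Per gene, a Wilcoxon rank-sum test on log2(x+1) values between the two
#' classes with BH adjustment, and the log2 fold change of class means
#' (pseudocount 1). Genes passing `pAdj < 0.05` and `|log2FC| > 1` are
#' sorted by `|log2FC|` and the top `n` returned; if fewer survive the
#' filter, all survivors are returned with a warning.
#'
#' @param expr an [ExpressionMatrix-class].
#' @param labels two-level [ClassLabels-class].
#' @param n number of classifier genes to keep (default 150).
#' @param pCut,fcCut filter thresholds (defaults 0.05 and 1).
#' @return data.frame with columns `gene`, `log2FC` (immune vs non-immune),
#'   `p`, `pAdj`, sorted by `|log2FC|` descending.
#' @export
classifierGenes <- function(expr, labels, n = 150L, pCut = 0.05, fcCut = 1) {
  lab <- sampleLabels(labels)[sampleIds(expr)]
  if (any(is.na(lab))) stop("labels missing for some samples")
  if (min(table(lab)) < 3L) stop("both classes need >= 3 samples")
  isImm <- lab == "immune" | lab %in% c("immune-activated", "immune-suppressed")
  lx <- logExpr(expr)
  v <- exprValues(expr)
  p <- apply(lx, 1, function(row) {
    if (length(unique(row)) == 1L) return(1)
    stats::wilcox.test(row[isImm], row[!isImm], exact = FALSE)$p.value
  })
  log2FC <- log2((rowMeans(v[, isImm, drop = FALSE]) + 1) /
                 (rowMeans(v[, !isImm, drop = FALSE]) + 1))
  pAdj <- stats::p.adjust(p, method = "BH")
  tab <- data.frame(gene = geneIds(expr), log2FC = log2FC, p = p, pAdj = pAdj,
                    row.names = NULL, stringsAsFactors = FALSE)
  keep <- tab$pAdj < pCut & abs(tab$log2FC) > fcCut
  tab <- tab[keep, , drop = FALSE]
  tab <- tab[order(-abs(tab$log2FC), tab$gene), , drop = FALSE]
  if (nrow(tab) < n)
    warning("only ", nrow(tab), " genes pass the filter (requested ", n, ")")
  utils::head(tab, n)
}

#' Classify a validation cohort with the transfer classifier
#'
#' k = 2 NMF consensus clustering on the classifier-gene submatrix of the
#' validation cohort, with the immune polarity set by the median immune
#' enrichment score exactly as in [discoverClasses()]. At least half of the
#' classifier genes must be present in the validation matrix.
#'
#' @param exprVal validation [ExpressionMatrix-class].
#' @param classifier data.frame from [classifierGenes()] (or any object with
#'   a `gene` column / character vector of genes).
#' @param immuneSignature [GeneSet-class] used to score the validation
#'   samples.
#' @param nRuns,seed,maxIter,tol consensus parameters.
#' @return A two-level [ClassLabels-class] with provenance `"transferred"`.
#' @export
transferClassify <- function(exprVal, classifier, immuneSignature,
                             nRuns = 30L, seed = 1L, maxIter = 2000L,
                             tol = 1e-6) {
  genes <- if (is.data.frame(classifier)) classifier$gene
           else as.character(classifier)
  if (ncol(exprVal) < 2L) stop("transfer classification needs >= 2 samples")
  present <- mean(toupper(genes) %in% toupper(geneIds(exprVal)))
  if (present < 0.5)
    stop(sprintf("classifier gene coverage %.2f below 0.5; missing: %s",
                 present,
                 paste(utils::head(setdiff(genes, geneIds(exprVal)), 10),
                       collapse = ", ")))
  scores <- immuneEnrichmentScore(exprVal, immuneSignature)
  res <- .twoClassConsensus(exprVal, genes, scores, nRuns, seed, maxIter,
                            tol, "transferred")
  out <- res$labels
  attr(out, "consensus") <- res$consensus
  out
}
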