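#' Single-sample gene-set enrichment score (ssGSEA)
#'
#' For each sample, genes are ranked by expression in descending order
#' (rank 1 = highest; ties receive average ranks). The enrichment score is
#' the running-sum statistic summed over all rank positions,
#' \deqn{ES = \sum_{i=1}^{N} [P_{hit}(i) - P_{miss}(i)],}
#' where \eqn{P_{hit}(i)} accumulates the rank-weighted (\eqn{rank^\alpha})
#' fraction of set genes at rank \eqn{\le i} and \eqn{P_{miss}(i)} the plain
#' fraction of non-set genes. Scores depend only on within-sample ranks, so
#' any strictly increasing transform of a sample's values leaves them
#' unchanged.
#'
#' Internally the double sum is evaluated in closed form: a gene at rank
#' \eqn{r} contributes to positions \eqn{i \ge r}, i.e.
#' \eqn{N - \lceil r \rceil + 1} positions, so
#' \deqn{ES = \frac{\sum_{g \in G} r_g^\alpha (N - \lceil r_g \rceil + 1)}
#'   {\sum_{g \in G} r_g^\alpha} -
#'   \frac{\sum_{g \notin G} (N - \lceil r_g \rceil + 1)}{N - |G|}.}
#'
#' @param expr an [ExpressionMatrix-class].
#' @param geneSet a [GeneSet-class].
#' @param alpha rank-weight exponent (default 0.25).
#' @param minOverlap minimum number of set genes that must be present.
#' @return named numeric vector of per-sample enrichment scores.
#' @export
ssgseaScore <- function(expr, geneSet, alpha = 0.25, minOverlap = 5L) {
  stopifnot(is(expr, "ExpressionMatrix"), is(geneSet, "GeneSet"))
  member <- geneIds(expr) %in% geneSet@genes
  nHit <- sum(member)
  if (nHit == 0L)
    stop("gene set '", geneSet@name, "' absent from the expression matrix")
  if (nHit < minOverlap)
    stop("gene set '", geneSet@name, "' has overlap ", nHit,
         " below the minimum of ", minOverlap)
  if (nHit == nrow(expr))
    stop("gene set '", geneSet@name, "' covers every gene; P_miss undefined")
  v <- exprValues(expr)
  vapply(seq_len(ncol(v)), function(j) {
    .esClosedForm(v[, j], member, alpha)
  }, numeric(1)) |> stats::setNames(sampleIds(expr))
}

# Closed-form running-sum ES for one sample (see ssgseaScore details).
.esClosedForm <- function(x, member, alpha) {
  n <- length(x)
  r <- rank(-x, ties.method = "average")
  span <- n - ceiling(r) + 1          # number of positions i with i >= r
  w <- r[member]^alpha
  hit <- sum(w * span[member]) / sum(w)
  miss <- sum(span[!member]) / (n - sum(member))
  hit - miss
}

#' Score a collection of signatures across samples
#'
#' Applies [ssgseaScore()] to every set in the collection. Sets whose overlap
#' with the matrix falls below `minOverlap` are dropped with a warning; if
#' all sets fail the filter an error lists them. With `normalize = TRUE` the
#' whole matrix is rescaled by its global `max - min` range (the usual
#' presentation for signature heatmaps).
#'
#' @param expr an [ExpressionMatrix-class].
#' @param collection a [SignatureCollection-class].
#' @param alpha rank-weight exponent.
#' @param normalize rescale scores by the global range.
#' @param minOverlap minimum set genes present (default 5).
#' @return A [ScoreMatrix-class] (signatures x samples).
#' @export
scoreSignatures <- function(expr, collection, alpha = 0.25, normalize = FALSE,
                            minOverlap = 5L) {
  stopifnot(is(collection, "SignatureCollection"))
  if (length(collection) == 0L) stop("empty signature collection")
  nms <- signatureNames(collection)
  rows <- vector("list", length(collection))
  kept <- logical(length(collection))
  for (i in seq_len(length(collection))) {
    res <- tryCatch(ssgseaScore(expr, collection[[i]], alpha = alpha,
                                minOverlap = minOverlap),
                    error = function(e) NULL)
    if (!is.null(res)) { rows[[i]] <- res; kept[i] <- TRUE }
  }
  if (!any(kept))
    stop("all signatures failed the overlap filter: ",
         paste(nms, collapse = ", "))
  if (any(!kept))
    warning("signature(s) dropped by the overlap filter: ",
            paste(nms[!kept], collapse = ", "))
  scores <- do.call(rbind, rows[kept])
  rownames(scores) <- nms[kept]
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  new("ScoreMatrix", scores = scores, alpha = alpha, normalized = normalize)
}

#' Per-sample immune enrichment score
#'
#' ssGSEA score (alpha = 0.25, unnormalized) of a single immune gene
#' signature, used as the per-sample immune-infiltration proxy throughout
#' the classification cascade. The package ships a curated immune signature
#' (`system.file("extdata", "immune_signature_synthetic.gmt", package =
#' "immunoclass")`) as a swappable stand-in for a published immune gene
#' list.
#'
#' @param expr an [ExpressionMatrix-class].
#' @param immuneSignature a [GeneSet-class] of immune genes.
#' @param minOverlap minimum signature genes present.
#' @return named numeric vector of per-sample scores.
#' @export
immuneEnrichmentScore <- function(expr, immuneSignature, minOverlap = 5L) {
  ssgseaScore(expr, immuneSignature, alpha = 0.25, minOverlap = minOverlap)
}
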