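#' Non-negative matrix factorization by multiplicative KL updates
#'
#' Factorizes a nonnegative matrix `X ~ W H` (genes x k times k x samples)
#' by the classic multiplicative update rules that monotonically decrease
#' the generalized Kullback-Leibler divergence
#' \deqn{D(X \| WH) = \sum_{ij} x_{ij} \log(x_{ij}/(WH)_{ij}) - x_{ij} + (WH)_{ij}.}
#' Initialization is random uniform from `seed`; iteration stops when the
#' relative loss change falls below `tol` or after `maxIter` updates. Rows or
#' columns that are entirely zero are dropped with a warning, since the
#' update rules divide by their marginals.
#'
#' @param x an [ExpressionMatrix-class] or nonnegative numeric matrix
#'   (linear scale; never log).
#' @param k factorization rank, `2 <= k < min(dim(x))`.
#' @param seed integer seed for the initialization.
#' @param maxIter maximum number of update sweeps (default 2000).
#' @param tol relative loss-change stopping tolerance (default 1e-6).
#' @return An [NMFResult-class].
#' @export
nmfFactorize <- function(x, k, seed = 1L, maxIter = 2000L, tol = 1e-6) {
  X <- if (is(x, "ExpressionMatrix")) exprValues(x) else as.matrix(x)
  if (min(X) < 0) stop("NMF requires a nonnegative matrix")
  zr <- rowSums(X) == 0
  zc <- colSums(X) == 0
  if (any(zr) || any(zc)) {
    warning(sum(zr), " all-zero row(s) and ", sum(zc),
            " all-zero column(s) dropped before factorization")
    X <- X[!zr, !zc, drop = FALSE]
  }
  n <- nrow(X); m <- ncol(X)
  k <- as.integer(k)
  if (k < 1L || k >= min(n, m)) stop("rank k must satisfy 1 <= k < min(dim)")
  eps <- .Machine$double.eps
  withSeed(seed, {
    W <- matrix(stats::runif(n * k), n, k)
    H <- matrix(stats::runif(k * m), k, m)
  })
  # put WH on the scale of X so the first iterations are well-conditioned
  H <- H * (mean(X) / mean(W %*% H))

  pos <- X > 0
  xPos <- X[pos]
  xlogx <- sum(xPos * log(xPos))
  sumX <- sum(X)
  klDiv <- function(WH) xlogx - sum(xPos * log(WH[pos])) - sumX + sum(WH)

  trace <- numeric(maxIter)
  prev <- Inf
  iter <- 0L
  WH <- W %*% H + eps
  while (iter < maxIter) {
    iter <- iter + 1L
    H <- H * crossprod(W, X / WH) / pmax(colSums(W), eps)
    WH <- W %*% H + eps
    W <- W * ((X / WH) %*% t(H)) / rep(pmax(rowSums(H), eps), each = n)
    WH <- W %*% H + eps
    cur <- klDiv(WH)
    trace[iter] <- cur
    if (is.finite(prev) && (prev - cur) < tol * max(abs(prev), eps)) break
    prev <- cur
  }
  trace <- trace[seq_len(iter)]
  rownames(W) <- rownames(X)
  colnames(W) <- paste0("F", seq_len(k))
  rownames(H) <- colnames(W)
  colnames(H) <- colnames(X)
  new("NMFResult", W = W, H = H, k = k, lossTrace = trace,
      seed = as.integer(seed), nIter = iter)
}

#' Assign each sample to its dominant factor
#'
#' The dominant factor is the argmax of the sample's column of `H`; exact
#' ties are broken toward the lowest factor index and flagged. The margin is
#' the top minus the second H weight.
#'
#' @param result an [NMFResult-class].
#' @return data.frame with columns `sample_id`, `factor`, `margin`, `tie`.
#' @export
assignFactors <- function(result) {
  stopifnot(is(result, "NMFResult"))
  H <- result@H
  idx <- apply(H, 2, which.max)
  top <- H[cbind(idx, seq_len(ncol(H)))]
  second <- vapply(seq_len(ncol(H)), function(j) {
    if (nrow(H) == 1L) 0 else max(H[-idx[j], j])
  }, numeric(1))
  tie <- vapply(seq_len(ncol(H)), function(j) sum(H[, j] == top[j]) > 1L,
                logical(1))
  data.frame(sample_id = colnames(H), factor = as.integer(idx),
             margin = top - second, tie = tie,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Multi-run NMF consensus clustering
#'
#' Runs `nRuns` factorizations from seeds `baseSeed .. baseSeed + nRuns - 1`,
#' builds the per-run sample connectivity matrix from dominant-factor
#' co-assignment, averages into a consensus matrix `C` in \[0, 1\], and cuts
#' average-linkage hierarchical clustering of `1 - C` into `k` groups.
#' Dispersion (`mean(4 (C - 1/2)^2)`, 1 for a perfectly crisp consensus) is
#' reported alongside.
#'
#' @param x an [ExpressionMatrix-class] or nonnegative matrix.
#' @param k rank and number of consensus groups (>= 2).
#' @param nRuns number of random restarts (default 30).
#' @param baseSeed first seed.
#' @param maxIter,tol forwarded to [nmfFactorize()].
#' @return list with `consensus` (samples x samples), `labels` (named integer
#'   cluster per sample), `dispersion`, `nRuns`.
#' @export
consensusNMF <- function(x, k, nRuns = 30L, baseSeed = 1L,
                         maxIter = 2000L, tol = 1e-6) {
  if (k < 2L) stop("consensus clustering requires k >= 2")
  X <- if (is(x, "ExpressionMatrix")) exprValues(x) else as.matrix(x)
  m <- ncol(X)
  if (m < 2L) stop("consensus clustering requires at least 2 samples")
  C <- matrix(0, m, m)
  for (r in seq_len(nRuns)) {
    fit <- nmfFactorize(X, k, seed = baseSeed + r - 1L,
                        maxIter = maxIter, tol = tol)
    f <- assignFactors(fit)$factor
    C <- C + outer(f, f, "==")
  }
  C <- C / nRuns
  dimnames(C) <- list(colnames(X), colnames(X))
  hc <- stats::hclust(stats::as.dist(1 - C), method = "average")
  labels <- stats::cutree(hc, k = k)
  names(labels) <- colnames(X)
  list(consensus = C, labels = labels,
       dispersion = mean(4 * (C - 0.5)^2), nRuns = nRuns)
}

#' Keep the most variable genes by median absolute deviation
#'
#' Standard prefilter before the full-rank microdissection run.
#'
#' @param expr an [ExpressionMatrix-class].
#' @param n number of genes to keep (default 5000).
#' @return An [ExpressionMatrix-class] restricted to the top-`n` MAD genes,
#'   original gene order preserved.
#' @export
madFilter <- function(expr, n = 5000L) {
  stopifnot(is(expr, "ExpressionMatrix"))
  if (nrow(expr) <= n) return(expr)
  mads <- apply(exprValues(expr), 1, stats::mad)
  keep <- rank(-mads, ties.method = "first") <= n
  expr[keep, ]
}
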