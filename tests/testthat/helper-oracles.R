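# Independent oracles used to freeze expected values. Each is a direct,
# naive implementation kept separate from the package's own code paths.

# ssGSEA running sum computed position by position over all N rank
# positions, exactly as the score is defined (descending ranks, average
# ties, hit weight rank^alpha).
esOracle <- function(x, member, alpha) {
  n <- length(x)
  r <- rank(-x, ties.method = "average")
  wTot <- sum(r[member]^alpha)
  nMiss <- n - sum(member)
  es <- 0
  for (i in seq_len(n)) {
    pHit <- sum(r[member & r <= i]^alpha) / wTot
    pMiss <- sum(!member & r <= i) / nMiss
    es <- es + pHit - pMiss
  }
  es
}

# Two-group log-rank chi-square from the observed-minus-expected sums.
logrankOracle <- function(time, event, group) {
  g <- sort(unique(group))
  stopifnot(length(g) == 2)
  eventTimes <- sort(unique(time[event == 1]))
  OmE <- 0; V <- 0
  for (t in eventTimes) {
    atRisk <- time >= t
    n <- sum(atRisk)
    n1 <- sum(atRisk & group == g[1])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g[1])
    OmE <- OmE + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  OmE^2 / V
}

# Fisher's exact two-sided p for a 2x2 table by exhaustive enumeration of
# all tables with the observed margins.
fisherOracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  aRange <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(aRange, r1, r2, c1)
  pObs <- dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Signal-to-noise ratio with the same variance floor the package documents.
snrOracle <- function(xin, xout) {
  muIn <- mean(xin); muOut <- mean(xout)
  fl <- function(s, mu) max(s, 0.2 * abs(mu), 0.2)
  (muIn - muOut) / (fl(sd(xin), muIn) + fl(sd(xout), muOut))
}

# Greedy maximum-cosine matching of fitted factor columns to planted ones;
# returns the mean matched cosine. Exhaustive over permutations for k <= 5.
matchedCosine <- function(W, W0) {
  k <- ncol(W0)
  cosMat <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    cosMat[i, j] <- sum(W[, i] * W0[, j]) /
      (sqrt(sum(W[, i]^2)) * sqrt(sum(W0[, j]^2)))
  }
  if (k <= 5) {
    perms <- .permutations(k)
    best <- -Inf
    for (p in seq_len(nrow(perms))) {
      v <- mean(cosMat[cbind(perms[p, ], seq_len(k))])
      if (v > best) best <- v
    }
    best
  } else {
    used <- logical(k); tot <- 0
    for (j in order(-apply(cosMat, 2, max))) {
      i <- which.max(ifelse(used, -Inf, cosMat[, j]))
      used[i] <- TRUE
      tot <- tot + cosMat[i, j]
    }
    tot / k
  }
}

.permutations <- function(k) {
  if (k == 1) return(matrix(1))
  sub <- .permutations(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, matrix(c(seq_len(k)[-i])[sub], nrow(sub)))
  }))
}

agreementRate <- function(a, b) mean(a[names(b)] == b)
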