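#' Nearest template prediction
#'
#' Expression is taken to the log2 scale and gene-wise z-standardized across
#' samples. For each sample and template the distance is `d = 1 - cos(x_G,
#' w_G)` over the template genes present in the matrix (`d` in \[0, 2\]).
#' Significance is by resampling: `nPerm` random gene sets of the same size
#' are drawn from all genes, and `p = (1 + #\{d_rand <= d_obs\}) / (1 +
#' nPerm)`, BH-adjusted across samples per template. Each sample is assigned
#' to the template with minimal distance; the `confident` flag marks
#' `q < qCut` for the assigned template. Templates with overlap below their
#' `minOverlap` are skipped with a warning (an error if all are skipped).
#'
#' @param expr an [ExpressionMatrix-class].
#' @param templates list of [NTPTemplate-class] objects.
#' @param nPerm number of random gene sets for the null (default 1000).
#' @param seed RNG seed for the resampling.
#' @param qCut FDR threshold for the `confident` flag (default 0.05).
#' @return list with `distance` (samples x templates), `p`, `q` (same
#'   shape), `assigned` (named character), `confident` (named logical).
#' @export
ntpClassify <- function(expr, templates, nPerm = 1000L, seed = 1L,
                        qCut = 0.05) {
  stopifnot(is(expr, "ExpressionMatrix"))
  if (is(templates, "NTPTemplate")) templates <- list(templates)
  stopifnot(all(vapply(templates, is, logical(1), "NTPTemplate")))
  if (nPerm < 1L) stop("nPerm must be >= 1")
  Z <- .rowStandardize(logExpr(expr))
  nS <- ncol(Z)
  tNames <- vapply(templates, function(t) t@name, character(1))
  keep <- logical(length(templates))
  D <- P <- matrix(NA_real_, nS, length(templates),
                   dimnames = list(colnames(Z), tNames))
  withSeed(seed, {
    for (ti in seq_along(templates)) {
      tpl <- templates[[ti]]
      idx <- match(tpl@genes, rownames(Z))
      ok <- !is.na(idx)
      if (sum(ok) < tpl@minOverlap) {
        warning("template '", tpl@name, "' overlap ", sum(ok),
                " below minimum ", tpl@minOverlap, "; skipped")
        next
      }
      keep[ti] <- TRUE
      w <- tpl@weights[ok]
      d <- .cosDistance(Z[idx[ok], , drop = FALSE], w)
      # shared null: random gene sets of equal size, signs kept
      nulls <- matrix(NA_real_, nPerm, nS)
      for (b in seq_len(nPerm)) {
        ridx <- sample.int(nrow(Z), sum(ok))
        nulls[b, ] <- .cosDistance(Z[ridx, , drop = FALSE], w)
      }
      D[, ti] <- d
      P[, ti] <- (1 + colSums(nulls <= rep(d, each = nPerm))) / (1 + nPerm)
    }
  })
  if (!any(keep)) stop("all templates skipped: insufficient gene overlap")
  D <- D[, keep, drop = FALSE]
  P <- P[, keep, drop = FALSE]
  Q <- apply(P, 2, stats::p.adjust, method = "BH")
  if (is.null(dim(Q))) Q <- matrix(Q, ncol = ncol(P), dimnames = dimnames(P))
  ai <- apply(D, 1, which.min)
  assigned <- colnames(D)[ai]
  names(assigned) <- rownames(D)
  confident <- Q[cbind(seq_len(nrow(Q)), ai)] < qCut
  names(confident) <- rownames(D)
  list(distance = D, p = P, q = Q, assigned = assigned, confident = confident)
}

# Gene-wise z across samples; constant genes get all-zero rows.
.rowStandardize <- function(m) {
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  sd[sd == 0] <- 1
  (m - mu) / sd
}

# Cosine distance of every column of zg to the weight vector w.
.cosDistance <- function(zg, w) {
  num <- as.vector(crossprod(zg, w))
  den <- sqrt(colSums(zg^2)) * sqrt(sum(w^2))
  den[den == 0] <- 1
  1 - num / den
}

#' Split the immune class by stromal activation
#'
#' Runs NTP on the immune-class samples only, contrasting the
#' activated-stroma template with its negation (all weights flipped), so
#' that the argmin assignment is a well-defined two-class decision.
#' Stroma-assigned samples become `"immune-suppressed"`, the rest
#' `"immune-activated"`; non-immune samples keep their label. All immune
#' samples are assigned (non-confident calls keep their minimal-distance
#' subclass; confidence is reported in the attached NTP result).
#'
#' @param expr an [ExpressionMatrix-class] (full cohort).
#' @param twoLevel two-level [ClassLabels-class].
#' @param stromaTemplate an [NTPTemplate-class] of activated-stroma genes.
#' @param nPerm,seed,qCut forwarded to [ntpClassify()].
#' @return A three-level [ClassLabels-class]; the immune-class NTP result is
#'   in attribute `"ntp"`.
#' @export
splitSubclasses <- function(expr, twoLevel, stromaTemplate, nPerm = 1000L,
                            seed = 1L, qCut = 0.05) {
  stopifnot(is(twoLevel, "ClassLabels"), is(stromaTemplate, "NTPTemplate"))
  lab <- sampleLabels(twoLevel)
  immuneSamples <- names(lab)[lab == "immune"]
  if (length(immuneSamples) < 10L)
    stop("immune class has fewer than 10 samples")
  sub <- expr[, match(immuneSamples, sampleIds(expr))]
  rest <- NTPTemplate(paste0("not-", stromaTemplate@name),
                      stromaTemplate@genes, -stromaTemplate@weights,
                      minOverlap = stromaTemplate@minOverlap)
  ntp <- ntpClassify(sub, list(stromaTemplate, rest), nPerm = nPerm,
                     seed = seed, qCut = qCut)
  newLab <- lab
  # require strictly smaller distance to the stroma template: a tie carries
  # no stromal evidence, so the sample stays immune-activated
  stromaAssigned <- rownames(ntp$distance)[
    ntp$assigned == stromaTemplate@name &
      ntp$distance[, stromaTemplate@name] < ntp$distance[, rest@name]]
  newLab[immuneSamples] <- "immune-activated"
  newLab[stromaAssigned] <- "immune-suppressed"
  out <- ClassLabels(names(newLab), unname(newLab),
                     provenance = provenance(twoLevel))
  attr(out, "ntp") <- ntp
  out
}

#' Immune-suppression profile of the subclasses
#'
#' Compares immune-suppressed against immune-activated samples, feature by
#' feature: signature rows come from a [ScoreMatrix-class], marker-gene rows
#' from log2(x+1) expression. Each row gets a two-sided Wilcoxon p-value,
#' BH-adjusted q across all rows, group medians and the direction of the
#' difference. Features absent from their source, or groups with fewer than
#' 3 samples, yield NA rows with a warning.
#'
#' @param scores a [ScoreMatrix-class] (signatures x samples).
#' @param labels three-level [ClassLabels-class].
#' @param signatures signature names to test (default: all rows of `scores`).
#' @param expr optional [ExpressionMatrix-class] supplying marker genes.
#' @param genes optional character vector of marker genes tested on
#'   log2(x+1) expression.
#' @return data.frame: `feature`, `type`, `medianSuppressed`,
#'   `medianActivated`, `direction`, `p`, `q`, `stars`.
#' @export
suppressionProfile <- function(scores, labels, signatures = NULL,
                               expr = NULL, genes = NULL) {
  stopifnot(is(scores, "ScoreMatrix"), is(labels, "ClassLabels"))
  lab <- sampleLabels(labels)
  if (!any(lab %in% c("immune-activated", "immune-suppressed")))
    stop("three-level labels required")
  if (is.null(signatures)) signatures <- signatureNames(scores)
  sup <- names(lab)[lab == "immune-suppressed"]
  act <- names(lab)[lab == "immune-activated"]
  groupsOk <- length(sup) >= 3L && length(act) >= 3L
  if (!groupsOk) warning("a subclass has fewer than 3 samples; NA rows returned")

  fetch <- function(feature, type) {
    if (type == "signature") {
      if (!feature %in% signatureNames(scores)) return(NULL)
      scoreValues(scores)[feature, ]
    } else {
      if (is.null(expr) || !feature %in% geneIds(expr)) return(NULL)
      logExpr(expr)[feature, ]
    }
  }
  features <- rbind(
    if (length(signatures))
      data.frame(feature = signatures, type = "signature"),
    if (length(genes)) data.frame(feature = genes, type = "gene"))
  rows <- lapply(seq_len(nrow(features)), function(i) {
    f <- features$feature[i]; ty <- features$type[i]
    v <- fetch(f, ty)
    if (is.null(v) || !groupsOk) {
      if (is.null(v)) warning("feature '", f, "' not found; NA row")
      return(data.frame(feature = f, type = ty, medianSuppressed = NA_real_,
                        medianActivated = NA_real_, direction = NA_character_,
                        p = NA_real_))
    }
    vs <- v[sup]; va <- v[act]
    p <- if (length(unique(c(vs, va))) == 1L) 1 else
      stats::wilcox.test(vs, va, exact = FALSE)$p.value
    data.frame(feature = f, type = ty,
               medianSuppressed = stats::median(vs),
               medianActivated = stats::median(va),
               direction = if (stats::median(vs) >= stats::median(va)) "up" else "down",
               p = p)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$stars <- ifelse(is.na(out$q), NA_character_, significanceStars(out$q))
  out
}
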