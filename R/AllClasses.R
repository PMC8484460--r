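#' @import methods
#' @importFrom S4Vectors metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
NULL

#' ExpressionMatrix: nonnegative genes x samples expression
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' single `exprs` assay of linear-scale, nonnegative expression values
#' (counts, TPM, or simulated intensities). Gene symbols are row names,
#' sample identifiers column names; both must be unique. A log2(x+1) view is
#' computed on demand with [logExpr()] rather than stored, because the NMF
#' stages require the linear nonnegative matrix while scoring and
#' differential expression operate on the log scale.
#'
#' @slot isLog logical; `TRUE` when the stored values are already on the
#'   log2 scale (in which case negativity is permitted).
#'
#' @seealso [readExpression()], [alignGenes()], [exprValues()]
#' @export
setClass("ExpressionMatrix",
  contains = "SummarizedExperiment",
  slots = c(isLog = "logical"),
  prototype = prototype(isLog = FALSE)
)

setValidity("ExpressionMatrix", function(object) {
  msg <- character()
  if (!"exprs" %in% assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  else {
    v <- assay(object, "exprs")
    if (is.null(rownames(v)) || is.null(colnames(v)))
      msg <- c(msg, "gene and sample identifiers are required")
    else {
      if (anyDuplicated(rownames(v)))
        msg <- c(msg, "duplicate gene identifiers")
      if (anyDuplicated(colnames(v)))
        msg <- c(msg, "duplicate sample identifiers")
    }
    if (!all(is.finite(v)))
      msg <- c(msg, "expression values must be finite")
    else if (!object@isLog && min(v) < 0)
      msg <- c(msg, "negative values in a linear-scale expression matrix")
  }
  if (length(object@isLog) != 1L)
    msg <- c(msg, "isLog must be a single logical")
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix (genes x samples) with dimnames, or the
#'   `geneIds`/`sampleIds` arguments supply them.
#' @param geneIds,sampleIds identifier vectors; default taken from dimnames.
#' @param isLog logical; set `TRUE` for log2-scale input.
#' @return An [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(rpois(6, 10), 3, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' ExpressionMatrix(m)
#' @export
ExpressionMatrix <- function(values, geneIds = rownames(values),
                             sampleIds = colnames(values), isLog = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(geneIds) || is.null(sampleIds))
    stop("gene and sample identifiers are required")
  rownames(values) <- as.character(geneIds)
  colnames(values) <- as.character(sampleIds)
  se <- SummarizedExperiment(assays = list(exprs = values))
  new("ExpressionMatrix", se, isLog = isLog)
}

#' GeneSet: a named set of gene symbols
#'
#' @slot name single character, the signature name.
#' @slot genes character vector of unique gene symbols (non-empty).
#' @slot direction `"up"` or `"unsigned"`.
#' @export
setClass("GeneSet",
  slots = c(name = "character", genes = "character", direction = "character"),
  prototype = prototype(direction = "unsigned")
)

setValidity("GeneSet", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "name must be a single non-empty string")
  if (length(object@genes) == 0L)
    msg <- c(msg, "gene set is empty")
  if (anyDuplicated(object@genes))
    msg <- c(msg, "duplicate genes in set")
  if (!object@direction %in% c("up", "unsigned"))
    msg <- c(msg, "direction must be 'up' or 'unsigned'")
  if (length(msg)) msg else TRUE
})

#' @rdname GeneSet-class
#' @param name,genes,direction see slots.
#' @export
GeneSet <- function(name, genes, direction = "unsigned") {
  new("GeneSet", name = as.character(name),
      genes = unique(as.character(genes)), direction = direction)
}

#' SignatureCollection: an ordered list of GeneSets with unique names
#'
#' @slot sets list of [GeneSet-class] objects.
#' @export
setClass("SignatureCollection", slots = c(sets = "list"))

setValidity("SignatureCollection", function(object) {
  if (!all(vapply(object@sets, is, logical(1), "GeneSet")))
    return("all elements must be GeneSet objects")
  nm <- vapply(object@sets, function(s) s@name, character(1))
  if (anyDuplicated(nm)) return("duplicate signature names")
  TRUE
})

#' @rdname SignatureCollection-class
#' @param sets list of [GeneSet-class] objects.
#' @export
SignatureCollection <- function(sets = list()) {
  new("SignatureCollection", sets = sets)
}

#' ClinicalTable: per-sample survival and covariate data
#'
#' Times are in days; events are 0 (censored) / 1 (event), with `NA` allowed
#' for the optional disease-free survival endpoint. MSI status takes values
#' `"MSI"`, `"MSS"` or `"unknown"`.
#'
#' @slot sampleIds unique sample identifiers.
#' @slot osTime,osEvent overall survival time (days, >= 0) and event flag.
#' @slot dfsTime,dfsEvent optional disease-free survival endpoint (NA when absent).
#' @slot msiStatus character vector in {MSI, MSS, unknown}.
#' @slot covariates data.frame of free clinical columns (age, sex, stage, ...).
#' @export
setClass("ClinicalTable",
  slots = c(sampleIds = "character", osTime = "numeric", osEvent = "numeric",
            dfsTime = "numeric", dfsEvent = "numeric", msiStatus = "character",
            covariates = "data.frame")
)

setValidity("ClinicalTable", function(object) {
  n <- length(object@sampleIds)
  msg <- character()
  if (anyDuplicated(object@sampleIds)) msg <- c(msg, "duplicate sample ids")
  for (s in c("osTime", "osEvent", "dfsTime", "dfsEvent", "msiStatus")) {
    if (length(slot(object, s)) != n)
      msg <- c(msg, sprintf("%s length does not match sample ids", s))
  }
  if (any(object@osTime < 0, na.rm = TRUE) || any(object@dfsTime < 0, na.rm = TRUE))
    msg <- c(msg, "survival times must be nonnegative")
  ev <- c(object@osEvent, object@dfsEvent)
  if (!all(ev %in% c(0, 1) | is.na(ev)))
    msg <- c(msg, "events must be 0/1")
  if (!all(object@msiStatus %in% c("MSI", "MSS", "unknown")))
    msg <- c(msg, "msiStatus values must be MSI/MSS/unknown")
  if (nrow(object@covariates) && nrow(object@covariates) != n)
    msg <- c(msg, "covariates row count does not match sample ids")
  if (length(msg)) msg else TRUE
})

#' @rdname ClinicalTable-class
#' @param sampleIds,osTime,osEvent,dfsTime,dfsEvent,msiStatus,covariates see slots.
#' @export
ClinicalTable <- function(sampleIds, osTime, osEvent,
                          dfsTime = rep(NA_real_, length(sampleIds)),
                          dfsEvent = rep(NA_real_, length(sampleIds)),
                          msiStatus = rep("unknown", length(sampleIds)),
                          covariates = data.frame()) {
  new("ClinicalTable", sampleIds = as.character(sampleIds),
      osTime = as.numeric(osTime), osEvent = as.numeric(osEvent),
      dfsTime = as.numeric(dfsTime), dfsEvent = as.numeric(dfsEvent),
      msiStatus = as.character(msiStatus), covariates = covariates)
}

#' ScoreMatrix: signatures x samples single-sample enrichment scores
#'
#' @slot scores numeric matrix, one row per signature that passed the
#'   minimum-overlap filter, one column per sample.
#' @slot alpha rank-weight exponent used by the ssGSEA running sum.
#' @slot normalized logical; `TRUE` when scores were rescaled by the global
#'   max - min range (values then lie in \[-1, 1\]).
#' @export
setClass("ScoreMatrix",
  slots = c(scores = "matrix", alpha = "numeric", normalized = "logical"),
  prototype = prototype(alpha = 0.25, normalized = FALSE)
)

setValidity("ScoreMatrix", function(object) {
  msg <- character()
  if (!all(is.finite(object@scores))) msg <- c(msg, "scores must be finite")
  if (is.null(rownames(object@scores)) || is.null(colnames(object@scores)))
    msg <- c(msg, "scores must carry signature and sample names")
  if (object@normalized && length(object@scores) &&
      (max(abs(object@scores)) > 1 + 1e-8))
    msg <- c(msg, "normalized scores must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' NMFResult: a single non-negative factorization X ~ W H
#'
#' @slot W nonnegative genes x k loading matrix.
#' @slot H nonnegative k x samples weight matrix.
#' @slot k factorization rank.
#' @slot lossTrace per-iteration generalized KL divergence (non-increasing).
#' @slot seed integer seed used for the random uniform initialization.
#' @slot nIter number of multiplicative updates actually run.
#' @export
setClass("NMFResult",
  slots = c(W = "matrix", H = "matrix", k = "integer", lossTrace = "numeric",
            seed = "integer", nIter = "integer")
)

setValidity("NMFResult", function(object) {
  msg <- character()
  if (min(object@W) < 0 || min(object@H) < 0)
    msg <- c(msg, "W and H must be nonnegative")
  if (!all(is.finite(object@W)) || !all(is.finite(object@H)))
    msg <- c(msg, "W and H must be finite")
  if (ncol(object@W) != object@k || nrow(object@H) != object@k)
    msg <- c(msg, "rank k inconsistent with W/H dimensions")
  d <- diff(object@lossTrace)
  if (length(d) && any(d > 1e-8 * abs(object@lossTrace[-length(object@lossTrace)]) + 1e-8))
    msg <- c(msg, "loss trace must be non-increasing")
  if (length(msg)) msg else TRUE
})

#' ClassLabels: per-sample immune class assignment
#'
#' Two-level labels take values `"immune"` / `"non-immune"`; three-level
#' labels split the immune class into `"immune-activated"` /
#' `"immune-suppressed"` while non-immune samples keep their label.
#'
#' @slot sampleIds sample identifiers.
#' @slot labels character vector of class labels.
#' @slot provenance one of `"discovery"`, `"refined"`, `"transferred"`.
#' @export
setClass("ClassLabels",
  slots = c(sampleIds = "character", labels = "character", provenance = "character")
)

.twoLevel <- c("immune", "non-immune")
.threeLevel <- c("immune-activated", "immune-suppressed", "non-immune")

setValidity("ClassLabels", function(object) {
  msg <- character()
  if (anyDuplicated(object@sampleIds)) msg <- c(msg, "duplicate sample ids")
  if (length(object@labels) != length(object@sampleIds))
    msg <- c(msg, "labels length does not match sample ids")
  ok2 <- all(object@labels %in% .twoLevel)
  ok3 <- all(object@labels %in% .threeLevel)
  if (!ok2 && !ok3)
    msg <- c(msg, "labels must form a two-level or three-level immune partition")
  if (!object@provenance %in% c("discovery", "refined", "transferred"))
    msg <- c(msg, "provenance must be discovery/refined/transferred")
  if (length(msg)) msg else TRUE
})

#' @rdname ClassLabels-class
#' @param sampleIds,labels,provenance see slots.
#' @export
ClassLabels <- function(sampleIds, labels, provenance = "discovery") {
  new("ClassLabels", sampleIds = as.character(sampleIds),
      labels = as.character(labels), provenance = provenance)
}

#' NTPTemplate: a signed template for nearest template prediction
#'
#' @slot name template name.
#' @slot genes template gene symbols.
#' @slot weights +1 (up) or -1 (down) per gene.
#' @slot minOverlap minimum number of template genes that must be present in
#'   the expression matrix for the template to be scored.
#' @export
setClass("NTPTemplate",
  slots = c(name = "character", genes = "character", weights = "numeric",
            minOverlap = "integer"),
  prototype = prototype(minOverlap = 5L)
)

setValidity("NTPTemplate", function(object) {
  msg <- character()
  if (length(object@genes) < 2L) msg <- c(msg, "template needs >= 2 genes")
  if (anyDuplicated(object@genes)) msg <- c(msg, "duplicate template genes")
  if (length(object@weights) != length(object@genes))
    msg <- c(msg, "weights length does not match genes")
  if (!all(object@weights %in% c(-1, 1)))
    msg <- c(msg, "weights must be +1 or -1")
  if (length(msg)) msg else TRUE
})

#' @rdname NTPTemplate-class
#' @param name,genes,weights,minOverlap see slots.
#' @export
NTPTemplate <- function(name, genes, weights = rep(1, length(genes)),
                        minOverlap = 5L) {
  new("NTPTemplate", name = as.character(name), genes = as.character(genes),
      weights = as.numeric(weights), minOverlap = as.integer(minOverlap))
}

#' SimulationConfig: parameters of the synthetic cohort generator
#'
#' Defaults mirror the composition of the cohort the classification was
#' developed on: about 43% of samples belong to the immune class and about
#' 53% of the immune class carries the activated-stroma (immune-suppressed)
#' program. Expression is a nonnegative rank-`kTrue` signal with
#' multiplicative lognormal noise; survival is exponential with
#' subclass-specific hazard multipliers (activated 0.6 < non-immune 1.0 <
#' suppressed 1.8 relative to a 1/1500 per-day baseline).
#'
#' @slot nGenes,nSamples matrix dimensions.
#' @slot kTrue number of latent programs.
#' @slot immuneFactorIndex index of the planted immune program.
#' @slot immuneFraction expected fraction of samples in the immune class.
#' @slot suppressedFraction expected fraction of immune samples that also
#'   carry the stromal program.
#' @slot immuneGeneCount,stromalGeneCount sizes of the planted gene programs.
#' @slot loadingScale multiplier on program loadings.
#' @slot noiseSigma sd of the lognormal multiplicative noise.
#' @slot baselineHazard events per day for the non-immune class.
#' @slot hazardActivated,hazardNonImmune,hazardSuppressed hazard multipliers.
#' @slot censoringRate expected fraction of samples censored.
#' @slot responderProbActivated,responderProbOther probability that a sample
#'   is an immunotherapy responder given its subclass.
#' @slot seed integer RNG seed.
#' @export
setClass("SimulationConfig",
  slots = c(nGenes = "integer", nSamples = "integer", kTrue = "integer",
            immuneFactorIndex = "integer", immuneFraction = "numeric",
            suppressedFraction = "numeric", immuneGeneCount = "integer",
            stromalGeneCount = "integer", loadingScale = "numeric",
            noiseSigma = "numeric", baselineHazard = "numeric",
            hazardActivated = "numeric", hazardNonImmune = "numeric",
            hazardSuppressed = "numeric", censoringRate = "numeric",
            responderProbActivated = "numeric", responderProbOther = "numeric",
            seed = "integer")
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@kTrue < 2L) msg <- c(msg, "kTrue must be >= 2")
  fr <- c(object@immuneFraction, object@suppressedFraction)
  if (any(fr <= 0 | fr >= 1)) msg <- c(msg, "fractions must lie in (0, 1)")
  if (object@immuneFactorIndex < 1L || object@immuneFactorIndex > object@kTrue)
    msg <- c(msg, "immuneFactorIndex out of range")
  if (object@immuneGeneCount + object@stromalGeneCount >= object@nGenes)
    msg <- c(msg, "immuneGeneCount + stromalGeneCount must be < nGenes")
  rates <- c(object@baselineHazard, object@hazardActivated,
             object@hazardNonImmune, object@hazardSuppressed)
  if (any(rates <= 0)) msg <- c(msg, "hazard rates must be positive")
  if (object@censoringRate < 0 || object@censoringRate >= 1)
    msg <- c(msg, "censoringRate must lie in [0, 1)")
  pr <- c(object@responderProbActivated, object@responderProbOther)
  if (any(pr < 0 | pr > 1)) msg <- c(msg, "responder probabilities must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname SimulationConfig-class
#' @param nGenes,nSamples,kTrue,immuneFactorIndex,immuneFraction,suppressedFraction,immuneGeneCount,stromalGeneCount,loadingScale,noiseSigma,baselineHazard,hazardActivated,hazardNonImmune,hazardSuppressed,censoringRate,responderProbActivated,responderProbOther,seed see slots.
#' @export
SimulationConfig <- function(nGenes = 2000L, nSamples = 300L, kTrue = 10L,
                             immuneFactorIndex = 7L, immuneFraction = 0.43,
                             suppressedFraction = 0.53, immuneGeneCount = 200L,
                             stromalGeneCount = 150L, loadingScale = 1,
                             noiseSigma = 0.3, baselineHazard = 1 / 1500,
                             hazardActivated = 0.6, hazardNonImmune = 1.0,
                             hazardSuppressed = 1.8, censoringRate = 0.2,
                             responderProbActivated = 0.8,
                             responderProbOther = 0.2, seed = 1L) {
  new("SimulationConfig", nGenes = as.integer(nGenes),
      nSamples = as.integer(nSamples), kTrue = as.integer(kTrue),
      immuneFactorIndex = as.integer(immuneFactorIndex),
      immuneFraction = immuneFraction, suppressedFraction = suppressedFraction,
      immuneGeneCount = as.integer(immuneGeneCount),
      stromalGeneCount = as.integer(stromalGeneCount),
      loadingScale = loadingScale, noiseSigma = noiseSigma,
      baselineHazard = baselineHazard, hazardActivated = hazardActivated,
      hazardNonImmune = hazardNonImmune, hazardSuppressed = hazardSuppressed,
      censoringRate = censoringRate,
      responderProbActivated = responderProbActivated,
      responderProbOther = responderProbOther, seed = as.integer(seed))
}
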