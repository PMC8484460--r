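# Accessor generics and show methods for the core classes.

#' @name accessors
#' @title Accessors for immunoclass objects
#' @description Slot access for the package's S4 classes; user code should
#'   use these rather than `@`.
#' @param x an immunoclass object.
NULL

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setMethod("exprValues", "ExpressionMatrix", function(x) assay(x, "exprs"))

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setMethod("geneIds", "ExpressionMatrix", function(x) rownames(x))
#' @rdname accessors
#' @export
setMethod("geneIds", "GeneSet", function(x) x@genes)

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setMethod("sampleIds", "ExpressionMatrix", function(x) colnames(x))
#' @rdname accessors
#' @export
setMethod("sampleIds", "ClinicalTable", function(x) x@sampleIds)
#' @rdname accessors
#' @export
setMethod("sampleIds", "ClassLabels", function(x) x@sampleIds)
#' @rdname accessors
#' @export
setMethod("sampleIds", "ScoreMatrix", function(x) colnames(x@scores))

#' @rdname accessors
#' @export
setGeneric("isLog", function(x) standardGeneric("isLog"))
#' @rdname accessors
#' @export
setMethod("isLog", "ExpressionMatrix", function(x) x@isLog)

#' log2(x + 1) view of an expression matrix
#'
#' Returns the stored matrix unchanged when it is already on the log scale.
#'
#' @param x an [ExpressionMatrix-class].
#' @return numeric matrix on the log2 scale.
#' @export
logExpr <- function(x) {
  stopifnot(is(x, "ExpressionMatrix"))
  v <- exprValues(x)
  if (isLog(x)) v else log2(v + 1)
}

#' @rdname accessors
#' @export
setGeneric("scoreValues", function(x) standardGeneric("scoreValues"))
#' @rdname accessors
#' @export
setMethod("scoreValues", "ScoreMatrix", function(x) x@scores)

#' @rdname accessors
#' @export
setGeneric("signatureNames", function(x) standardGeneric("signatureNames"))
#' @rdname accessors
#' @export
setMethod("signatureNames", "ScoreMatrix", function(x) rownames(x@scores))
#' @rdname accessors
#' @export
setMethod("signatureNames", "SignatureCollection",
          function(x) vapply(x@sets, function(s) s@name, character(1)))

#' @rdname accessors
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))
#' @rdname accessors
#' @export
setMethod("sampleLabels", "ClassLabels", function(x) {
  structure(x@labels, names = x@sampleIds)
})

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setMethod("provenance", "ClassLabels", function(x) x@provenance)

#' @rdname accessors
#' @export
setGeneric("basisMatrix", function(x) standardGeneric("basisMatrix"))
#' @rdname accessors
#' @export
setMethod("basisMatrix", "NMFResult", function(x) x@W)

#' @rdname accessors
#' @export
setGeneric("coefMatrix", function(x) standardGeneric("coefMatrix"))
#' @rdname accessors
#' @export
setMethod("coefMatrix", "NMFResult", function(x) x@H)

#' @rdname accessors
#' @export
setGeneric("lossTrace", function(x) standardGeneric("lossTrace"))
#' @rdname accessors
#' @export
setMethod("lossTrace", "NMFResult", function(x) x@lossTrace)

#' @param object object to display.
#' @rdname accessors
#' @export
setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%s scale)\n",
              nrow(object), ncol(object),
              if (object@isLog) "log2" else "linear"))
})

#' @rdname accessors
#' @export
setMethod("show", "GeneSet", function(object) {
  cat(sprintf("GeneSet '%s' (%s): %d genes\n", object@name,
              object@direction, length(object@genes)))
})

#' @rdname accessors
#' @export
setMethod("show", "SignatureCollection", function(object) {
  cat(sprintf("SignatureCollection: %d gene sets\n", length(object@sets)))
  nm <- signatureNames(object)
  if (length(nm)) cat("  ", paste(utils::head(nm, 8), collapse = ", "),
                      if (length(nm) > 8) ", ..." else "", "\n", sep = "")
})

#' @rdname accessors
#' @export
setMethod("show", "ScoreMatrix", function(object) {
  cat(sprintf("ScoreMatrix: %d signatures x %d samples (alpha=%g%s)\n",
              nrow(object@scores), ncol(object@scores), object@alpha,
              if (object@normalized) ", normalized" else ""))
})

#' @rdname accessors
#' @export
setMethod("show", "NMFResult", function(object) {
  cat(sprintf("NMFResult: %d genes x %d samples, rank %d, %d iterations, final KL %.6g\n",
              nrow(object@W), ncol(object@H), object@k, object@nIter,
              utils::tail(object@lossTrace, 1)))
})

#' @rdname accessors
#' @export
setMethod("show", "ClassLabels", function(object) {
  tb <- table(object@labels)
  cat(sprintf("ClassLabels (%s): %d samples\n", object@provenance,
              length(object@sampleIds)))
  for (nm in names(tb)) cat(sprintf("  %s: %d\n", nm, tb[[nm]]))
})

#' @rdname accessors
#' @export
setMethod("show", "ClinicalTable", function(object) {
  cat(sprintf("ClinicalTable: %d samples, %d OS events%s\n",
              length(object@sampleIds), sum(object@osEvent == 1, na.rm = TRUE),
              if (all(is.na(object@dfsTime))) "" else
                sprintf(", %d DFS events", sum(object@dfsEvent == 1, na.rm = TRUE))))
})

#' @rdname accessors
#' @export
setMethod("show", "NTPTemplate", function(object) {
  cat(sprintf("NTPTemplate '%s': %d genes (%d up, %d down)\n", object@name,
              length(object@genes), sum(object@weights > 0),
              sum(object@weights < 0)))
})

#' Number of gene sets in a collection
#' @param x a [SignatureCollection-class].
#' @export
setMethod("length", "SignatureCollection", function(x) length(x@sets))

#' Extract one gene set by position or name
#' @param x a [SignatureCollection-class].
#' @param i index or signature name.
#' @export
setMethod("[[", "SignatureCollection", function(x, i) {
  if (is.character(i)) {
    j <- match(i, signatureNames(x))
    if (is.na(j)) stop("no gene set named '", i, "'")
    i <- j
  }
  x@sets[[i]]
})

#' Convert a ClinicalTable to a data.frame
#' @param x a [ClinicalTable-class].
#' @param ... unused.
#' @export
setMethod("as.data.frame", "ClinicalTable", function(x, ...) {
  df <- data.frame(sample_id = x@sampleIds, os_time = x@osTime,
                   os_event = x@osEvent, dfs_time = x@dfsTime,
                   dfs_event = x@dfsEvent, msi_status = x@msiStatus,
                   stringsAsFactors = FALSE)
  if (nrow(x@covariates)) df <- cbind(df, x@covariates)
  df
})
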