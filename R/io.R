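#' Read an expression matrix from TSV or GCT
#'
#' TSV input has a header row of sample identifiers and gene symbols in the
#' first column. GCT v1.2 input starts with a `#1.2` line and a dimensions
#' line; the `Description` column is dropped. Duplicate gene rows are
#' collapsed by their mean, keeping first-occurrence order.
#'
#' @param path file path.
#' @param format `"tsv"` or `"gct"`; the default guesses from the extension.
#' @param isLog set `TRUE` when the stored values are log2-scale (negative
#'   values are then permitted).
#' @return An [ExpressionMatrix-class].
#' @export
readExpression <- function(path, format = c("auto", "tsv", "gct"),
                           isLog = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.gct$", path, ignore.case = TRUE)) "gct" else "tsv"
  if (format == "gct") {
    hdr <- readLines(path, n = 2L)
    if (length(hdr) < 2L || trimws(hdr[1]) != "#1.2")
      stop("malformed GCT header at line 1: expected '#1.2'")
    dims <- suppressWarnings(as.integer(strsplit(hdr[2], "\t")[[1]][1:2]))
    if (any(is.na(dims)))
      stop("malformed GCT dimensions at line 2")
    df <- utils::read.delim(path, skip = 2L, check.names = FALSE,
                            stringsAsFactors = FALSE)
    genes <- as.character(df[[1]])
    vals <- as.matrix(df[, -(1:2), drop = FALSE])
    if (nrow(vals) != dims[1] || ncol(vals) != dims[2])
      stop("GCT dimensions line disagrees with the data block")
  } else {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("malformed header at line 1: need gene column plus samples")
    genes <- as.character(df[[1]])
    vals <- as.matrix(df[, -1, drop = FALSE])
  }
  if (!is.numeric(vals)) stop("non-numeric expression values in ", path)
  if (anyDuplicated(genes)) {
    first <- !duplicated(genes)
    collapsed <- rowsum(vals, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
    vals <- collapsed
    genes <- unique(genes)
    message(sum(!first), " duplicate gene rows collapsed by mean")
  }
  rownames(vals) <- genes
  ExpressionMatrix(vals, isLog = isLog)
}

#' Write an expression matrix as TSV
#'
#' @param x an [ExpressionMatrix-class].
#' @param path output file path.
#' @param geneColumn name of the first (gene symbol) column.
#' @export
writeExpression <- function(x, path, geneColumn = "gene") {
  stopifnot(is(x, "ExpressionMatrix"))
  df <- data.frame(geneIds(x), exprValues(x), check.names = FALSE)
  colnames(df)[1] <- geneColumn
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene signatures from a GMT file
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`; empty gene
#' fields are dropped and duplicate genes within a set collapsed.
#'
#' @param path GMT file path.
#' @param direction direction recorded on every set (`"unsigned"` or `"up"`).
#' @return A [SignatureCollection-class].
#' @export
readGMT <- function(path, direction = "unsigned") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop(sprintf("GMT parse error at line %d: fewer than 3 fields", i))
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (!length(genes))
      stop(sprintf("GMT parse error at line %d: no genes", i))
    sets[[i]] <- GeneSet(fields[1], genes, direction = direction)
  }
  SignatureCollection(sets)
}

#' Write a SignatureCollection as GMT
#'
#' @param collection a [SignatureCollection-class].
#' @param path output file path.
#' @param descriptions optional description field per set (defaults to "na").
#' @export
writeGMT <- function(collection, path, descriptions = NULL) {
  stopifnot(is(collection, "SignatureCollection"))
  if (is.null(descriptions)) descriptions <- rep("na", length(collection))
  lines <- vapply(seq_len(length(collection)), function(i) {
    s <- collection[[i]]
    paste(c(s@name, descriptions[i], s@genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical table from TSV
#'
#' Requires columns `sample_id`, `os_time`, `os_event`; `dfs_time`/`dfs_event`
#' and `msi_status` are optional (MSI status defaults to `"unknown"`), and any
#' further columns are kept as covariates. Rows whose survival fields do not
#' parse (negative times, events outside 0/1) are excluded with a warning
#' giving the count.
#'
#' @param path TSV file path.
#' @return A [ClinicalTable-class].
#' @export
readClinical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("sample_id", "os_time", "os_event")
  missing <- setdiff(required, colnames(df))
  if (length(missing))
    stop("clinical table is missing required column(s): ",
         paste(missing, collapse = ", "))
  osTime <- suppressWarnings(as.numeric(df$os_time))
  osEvent <- suppressWarnings(as.numeric(df$os_event))
  bad <- is.na(osTime) | is.na(osEvent) | osTime < 0 | !(osEvent %in% c(0, 1))
  if (any(bad)) {
    warning(sum(bad), " row(s) with unparseable survival fields excluded")
    df <- df[!bad, , drop = FALSE]
    osTime <- osTime[!bad]; osEvent <- osEvent[!bad]
  }
  n <- nrow(df)
  getNum <- function(col) {
    if (col %in% colnames(df)) suppressWarnings(as.numeric(df[[col]]))
    else rep(NA_real_, n)
  }
  msi <- if ("msi_status" %in% colnames(df)) {
    m <- toupper(trimws(as.character(df$msi_status)))
    ifelse(m %in% c("MSI", "MSI-H", "MSI-L"), "MSI",
           ifelse(m == "MSS", "MSS", "unknown"))
  } else rep("unknown", n)
  covCols <- setdiff(colnames(df), c(required, "dfs_time", "dfs_event", "msi_status"))
  ClinicalTable(sampleIds = df$sample_id, osTime = osTime, osEvent = osEvent,
                dfsTime = getNum("dfs_time"), dfsEvent = getNum("dfs_event"),
                msiStatus = msi,
                covariates = df[, covCols, drop = FALSE])
}

#' Restrict an expression matrix to a reference gene list
#'
#' Returns the submatrix of genes present in `referenceGenes`, in reference
#' order; the achieved coverage fraction (matched / reference length) is
#' stored in `metadata(x)$coverage` and retrievable with
#' [alignmentCoverage()]. Matching is exact by symbol, optionally
#' case-insensitive (first occurrence wins).
#'
#' @param expr an [ExpressionMatrix-class].
#' @param referenceGenes character vector of gene symbols.
#' @param caseInsensitive match symbols after upper-casing.
#' @param minCoverage emit a warning when coverage falls below this floor.
#' @return An [ExpressionMatrix-class] restricted to the matched genes.
#' @export
alignGenes <- function(expr, referenceGenes, caseInsensitive = TRUE,
                       minCoverage = 0.5) {
  stopifnot(is(expr, "ExpressionMatrix"))
  referenceGenes <- as.character(referenceGenes)
  have <- geneIds(expr)
  idx <- if (caseInsensitive) match(toupper(referenceGenes), toupper(have))
         else match(referenceGenes, have)
  matched <- !is.na(idx)
  if (!any(matched))
    stop("no reference genes found in the expression matrix")
  coverage <- mean(matched)
  if (coverage < minCoverage)
    warning(sprintf("gene coverage %.2f below floor %.2f (%d of %d matched)",
                    coverage, minCoverage, sum(matched), length(referenceGenes)))
  out <- expr[idx[matched], ]
  metadata(out)$coverage <- coverage
  out
}

#' @rdname alignGenes
#' @param x an aligned [ExpressionMatrix-class].
#' @export
alignmentCoverage <- function(x) {
  cov <- metadata(x)$coverage
  if (is.null(cov)) NA_real_ else cov
}
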