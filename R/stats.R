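#' Kaplan-Meier curves and the log-rank test across classes
#'
#' Product-limit survival estimates per class and the k-group log-rank test
#' (chi-square with k-1 degrees of freedom, two-sided p), via the survival
#' package. Samples are matched between the clinical table and the labels by
#' identifier; classes with no subjects are dropped with a warning.
#'
#' @param clinical a [ClinicalTable-class].
#' @param labels a [ClassLabels-class] or named character vector.
#' @param endpoint `"OS"` or `"DFS"`.
#' @return list with `groups`, `curves` (data.frame: `group`, `time`,
#'   `surv`, `nRisk`, `nEvent`), `chisq`, `df`, `p`, and the underlying
#'   `survfit`/`survdiff` objects.
#' @export
kmLogrank <- function(clinical, labels, endpoint = c("OS", "DFS")) {
  endpoint <- match.arg(endpoint)
  stopifnot(is(clinical, "ClinicalTable"))
  lab <- if (is(labels, "ClassLabels")) sampleLabels(labels) else labels
  ids <- intersect(sampleIds(clinical), names(lab))
  if (!length(ids)) stop("no samples shared between clinical table and labels")
  i <- match(ids, sampleIds(clinical))
  time <- if (endpoint == "OS") clinical@osTime[i] else clinical@dfsTime[i]
  event <- if (endpoint == "OS") clinical@osEvent[i] else clinical@dfsEvent[i]
  if (all(is.na(time))) stop(endpoint, " endpoint columns are missing")
  ok <- !is.na(time) & !is.na(event)
  df <- data.frame(time = time[ok], event = event[ok],
                   group = factor(lab[ids][ok]))
  empty <- setdiff(levels(df$group), as.character(unique(df$group)))
  if (length(empty)) {
    warning("group(s) with zero subjects dropped: ",
            paste(empty, collapse = ", "))
    df$group <- droplevels(df$group)
  }
  if (nlevels(df$group) < 2L) stop("need >= 2 groups with subjects")
  if (sum(df$event) < 2L) stop("need >= 2 events overall")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  dfree <- length(sd$n) - 1L
  p <- stats::pchisq(sd$chisq, df = dfree, lower.tail = FALSE)
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  ss <- summary(sf)
  curves <- data.frame(group = sub("^group=", "", as.character(ss$strata)),
                       time = ss$time, surv = ss$surv, nRisk = ss$n.risk,
                       nEvent = ss$n.event, stringsAsFactors = FALSE)
  list(groups = levels(df$group), curves = curves,
       chisq = unname(sd$chisq), df = dfree, p = p,
       survfit = sf, survdiff = sd)
}

#' Contingency test of class composition
#'
#' Pearson chi-square (no continuity correction) or Fisher's exact test on a
#' counts table. `method = "auto"` uses Fisher when any expected cell count
#' is below 5, chi-square otherwise. For 2x2 tables the sample odds ratio
#' `(ad)/(bc)` is reported regardless of the test.
#'
#' @param table matrix (or object coercible to one) of nonnegative integer
#'   counts, 2x2 or r x c.
#' @param method `"auto"`, `"chisq"` or `"fisher"`.
#' @return list with `observed`, `method`, `statistic` (NA for Fisher),
#'   `p`, `oddsRatio` (NA unless 2x2), `expected`.
#' @export
contingencyTest <- function(table, method = c("auto", "chisq", "fisher")) {
  method <- match.arg(method)
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be nonnegative integers")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (method == "auto")
    method <- if (any(expected < 5)) "fisher" else "chisq"
  if (method == "chisq") {
    ht <- stats::chisq.test(tab, correct = FALSE)
    statistic <- unname(ht$statistic)
  } else {
    ht <- stats::fisher.test(tab)
    statistic <- NA_real_
  }
  oddsRatio <- if (all(dim(tab) == c(2L, 2L))) {
    (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  } else NA_real_
  list(observed = tab, method = method, statistic = statistic,
       p = unname(ht$p.value), oddsRatio = oddsRatio, expected = expected)
}

#' Compare signature scores between classes
#'
#' Per signature row of the score matrix, tests the difference between the
#' label groups: Student's t or Wilcoxon rank-sum for two groups,
#' Kruskal-Wallis for any number. p-values are BH-adjusted across
#' signatures and mapped to star annotations (ns p > 0.05 through
#' **** p < 0.0001). Constant-score signatures get p = 1 and a flag.
#'
#' @param scores a [ScoreMatrix-class].
#' @param labels a [ClassLabels-class] or named character vector.
#' @param test `"t"`, `"wilcoxon"` or `"kruskal"`.
#' @return data.frame with one row per signature: per-group means and
#'   medians, `p`, `q`, `stars`, `constant`.
#' @export
compareScores <- function(scores, labels, test = c("wilcoxon", "t", "kruskal")) {
  test <- match.arg(test)
  stopifnot(is(scores, "ScoreMatrix"))
  lab <- if (is(labels, "ClassLabels")) sampleLabels(labels) else labels
  lab <- lab[sampleIds(scores)]
  if (any(is.na(lab))) stop("labels missing for some scored samples")
  groups <- sort(unique(lab))
  if (length(groups) < 2L) stop("need >= 2 groups")
  if (any(table(lab) < 3L)) stop("every group needs >= 3 samples")
  if (test %in% c("t", "wilcoxon") && length(groups) != 2L)
    stop("'", test, "' requires exactly 2 groups; use 'kruskal'")
  S <- scoreValues(scores)
  rows <- lapply(rownames(S), function(sig) {
    v <- S[sig, ]
    constant <- length(unique(v)) == 1L
    p <- if (constant) 1 else switch(test,
      t = stats::t.test(v[lab == groups[1]], v[lab == groups[2]])$p.value,
      wilcoxon = stats::wilcox.test(v[lab == groups[1]], v[lab == groups[2]],
                                    exact = FALSE)$p.value,
      kruskal = stats::kruskal.test(v, factor(lab))$p.value)
    stats <- unlist(lapply(groups, function(g)
      c(mean(v[lab == g]), stats::median(v[lab == g]))))
    names(stats) <- as.vector(rbind(paste0("mean_", groups),
                                    paste0("median_", groups)))
    c(list(signature = sig), as.list(stats), list(p = p, constant = constant))
  })
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, check.names = FALSE)))
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$stars <- significanceStars(out$p)
  out
}
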