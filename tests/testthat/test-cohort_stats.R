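test_that("log-rank matches the observed-minus-expected oracle exactly", {
  # 6 + 6 subjects, mixed censoring
  time <- c(3, 6, 8, 12, 15, 20, 5, 7, 9, 11, 14, 18)
  event <- c(1, 1, 0, 1, 0, 1, 1, 1, 1, 0, 1, 1)
  group <- rep(c("A", "B"), each = 6)
  ids <- sprintf("p%02d", 1:12)
  clin <- ClinicalTable(ids, time, event)
  labels <- setNames(group, ids)
  res <- kmLogrank(clin, labels, "OS")
  expect_equal(res$chisq, logrankOracle(time, event, group), tolerance = 1e-9)
  expect_identical(res$df, 1L)
  expect_equal(res$p, pchisq(res$chisq, 1, lower.tail = FALSE), tolerance = 1e-12)
  # KM curves start at 1 and are non-increasing within group
  for (g in unique(res$curves$group)) {
    s <- res$curves$surv[res$curves$group == g]
    expect_true(all(diff(s) <= 1e-12))
    expect_lte(s[1], 1)
  }
})

test_that("log-rank is invariant to time rescaling and group relabeling", {
  set.seed(20)
  time <- rexp(40, 0.01); event <- rbinom(40, 1, 0.8)
  ids <- sprintf("q%02d", 1:40)
  group <- rep(c("x", "y"), 20)
  r1 <- kmLogrank(ClinicalTable(ids, time, event), setNames(group, ids))
  r2 <- kmLogrank(ClinicalTable(ids, time * 365, event), setNames(group, ids))
  expect_equal(r1$chisq, r2$chisq, tolerance = 1e-9)
  swapped <- ifelse(group == "x", "y", "x")
  r3 <- kmLogrank(ClinicalTable(ids, time, event), setNames(swapped, ids))
  expect_equal(r1$p, r3$p, tolerance = 1e-12)
})

test_that("identical groups give statistic 0 and p 1", {
  time <- c(5, 10, 15, 20); event <- c(1, 1, 0, 1)
  ids <- sprintf("d%02d", 1:8)
  clin <- ClinicalTable(ids, rep(time, 2), rep(event, 2))
  labels <- setNames(rep(c("g1", "g2"), each = 4), ids)
  res <- kmLogrank(clin, labels)
  expect_equal(res$chisq, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-12)
})

test_that("log-rank detects the planted hazard contrast with power", {
  # suppressed (1.8x) vs activated (0.6x) relative hazards, n = 100 each
  base <- 1 / 1500
  reject <- vapply(1:50, function(s) {
    set.seed(700 + s)
    tE <- c(rexp(100, base * 1.8), rexp(100, base * 0.6))
    tC <- rexp(200, base * 1.2 * 0.25)   # about 20% censoring
    time <- pmin(tE, tC); event <- as.numeric(tE <= tC)
    ids <- sprintf("s%03d", 1:200)
    res <- kmLogrank(ClinicalTable(ids, time, event),
                     setNames(rep(c("suppressed", "activated"), each = 100), ids))
    res$p < 0.05
  }, logical(1))
  expect_gte(mean(reject), 0.8)
})

test_that("contingency tests reproduce printed class enrichments", {
  # immune vs non-immune class composition tables
  tables <- list(
    C2 = rbind(c(48, 142), c(24, 212)),
    C1 = rbind(c(130, 60), c(201, 35)),
    CMS4 = rbind(c(60, 130), c(43, 193)),
    CMS2 = rbind(c(62, 128), c(120, 116)))
  for (nm in names(tables)) {
    res <- contingencyTest(tables[[nm]])
    expect_identical(res$method, "chisq")
    expect_lt(res$p, 0.01)
  }
})

test_that("contingency mechanics: balanced table, Fisher oracle, input checks", {
  bal <- contingencyTest(rbind(c(10, 10), c(10, 10)))
  expect_equal(bal$p, 1, tolerance = 1e-12)
  expect_equal(bal$oddsRatio, 1, tolerance = 1e-12)

  tab <- rbind(c(5, 0), c(0, 5))
  fi <- contingencyTest(tab, method = "fisher")
  expect_equal(fi$p, fisherOracle(tab), tolerance = 1e-12)
  auto <- contingencyTest(tab)       # expected counts 2.5 -> fisher
  expect_identical(auto$method, "fisher")

  expect_error(contingencyTest(rbind(c(-1, 2), c(3, 4))), "nonnegative")
  expect_error(contingencyTest(rbind(c(1.5, 2), c(3, 4))), "integer")
})

test_that("2x2 chi-square equals the squared two-proportion z statistic", {
  set.seed(30)
  for (i in 1:10) {
    tab <- matrix(sample(5:80, 4), 2)
    chi <- contingencyTest(tab, method = "chisq")$statistic
    n1 <- sum(tab[1, ]); n2 <- sum(tab[2, ])
    p1 <- tab[1, 1] / n1; p2 <- tab[2, 1] / n2
    pPool <- sum(tab[, 1]) / (n1 + n2)
    z <- (p1 - p2) / sqrt(pPool * (1 - pPool) * (1 / n1 + 1 / n2))
    expect_equal(chi, z^2, tolerance = 1e-9)
  }
})

test_that("score comparisons find planted immune signatures and stay calibrated", {
  run <- smallRun()
  cohort <- run$cohort
  sm <- scoreSignatures(cohort$expr, cohort$signatures)
  lab2 <- sampleLabels(run$res$twoLevel)
  tab <- compareScores(sm, run$res$twoLevel, test = "wilcoxon")
  immRow <- tab[tab$signature == "IMMUNE_TRUE", ]
  expect_lt(immRow$q, 0.05)
  expect_gt(immRow$mean_immune, immRow$`mean_non-immune`)
  expect_true(all(tab$q >= tab$p - 1e-12))
  # BH step-up: q is the running minimum of n*p/rank from the largest p down
  ord <- order(tab$p)
  n <- nrow(tab)
  qManual <- rev(cummin(rev(tab$p[ord] * n / seq_len(n))))
  expect_equal(tab$q[ord], pmin(qManual, 1), tolerance = 1e-12)

  # permuted labels: about 5% of signatures nominally significant
  fracs <- vapply(1:20, function(s) {
    set.seed(800 + s)
    perm <- setNames(sample(lab2), names(lab2))
    mean(compareScores(sm, perm, test = "wilcoxon")$p < 0.05)
  }, numeric(1))
  expect_lte(mean(fracs), 0.07)
})

test_that("identical groups and constant signatures are flagged", {
  sc <- rbind(sig = c(10, 10, 20, 20, 30, 30),  # groups share a distribution
              flat = rep(7, 6))
  colnames(sc) <- paste0("s", 1:6)
  sm <- new("ScoreMatrix", scores = sc, alpha = 0.25, normalized = FALSE)
  lab <- setNames(rep(c("u", "v"), 3), colnames(sc))
  tab <- compareScores(sm, lab, test = "wilcoxon")
  expect_equal(tab$p[tab$signature == "sig"], 1, tolerance = 1e-12)
  expect_true(tab$constant[tab$signature == "flat"])
  expect_equal(tab$p[tab$signature == "flat"], 1)
  expect_identical(tab$stars[tab$signature == "flat"], "ns")
})

test_that("star mapping follows the conventional cutpoints", {
  expect_identical(significanceStars(c(0.2, 0.051, 0.04, 0.009, 9e-4, 9e-5)),
                   c("ns", "ns", "*", "**", "***", "****"))
})
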