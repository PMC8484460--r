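test_that("immune factor selection follows the group-median argmax", {
  assignment <- data.frame(
    sample_id = paste0("s", 1:9),
    factor = rep(1:3, each = 3))
  scores <- setNames(c(10, 11, 12, 1, 2, 3, 4, 5, 6), assignment$sample_id)
  rep1 <- selectImmuneFactor(assignment, scores)
  expect_identical(rep1$chosenFactor, 1L)
  expect_lt(rep1$kruskalP, 0.05)

  # identical distributions in two factors: argmax by median, flag raised
  flat <- setNames(rep(c(5, 6, 7), 2), paste0("s", 1:6))
  a2 <- data.frame(sample_id = paste0("s", 1:6), factor = rep(1:2, each = 3))
  rep2 <- selectImmuneFactor(a2, flat)
  expect_true(rep2$notSignificant)

  a3 <- rbind(assignment, data.frame(sample_id = "s10", factor = 4))
  expect_warning(selectImmuneFactor(a3, c(scores, s10 = 99)), "excluded")
})

test_that("exemplar score is the load difference to the best other factor", {
  W <- rbind(immGene = c(5, 2, 1), other = c(1, 6, 2), weak = c(2, 1.5, 1.9))
  colnames(W) <- paste0("F", 1:3)
  ex <- exemplarScores(W, 1, topN = 2)
  expect_equal(unname(ex$scores["immGene"]), 3)
  expect_equal(unname(ex$scores["other"]), -5)
  expect_lt(ex$scores["other"], min(ex$scores[c("immGene", "weak")]))
  expect_identical(ex$selected, c("immGene", "weak"))
  expect_error(exemplarScores(W, 5), "out of range")

  # permuting the non-immune columns leaves scores unchanged
  ex2 <- exemplarScores(W[, c(1, 3, 2)], 1, topN = 2)
  expect_equal(ex2$scores, ex$scores)
})

test_that("exemplar genes come from the planted immune program", {
  run <- smallRun()
  frac <- mean(run$res$exemplars$selected %in% run$cohort$truth$immuneGenes)
  expect_gte(frac, 0.8)
})

test_that("class discovery recovers the planted immune split", {
  run <- smallRun()
  truth <- run$cohort$truth$class
  lab <- sampleLabels(run$res$twoLevel)
  expect_gte(agreementRate(lab, truth), 0.9)
  # labels partition the cohort
  expect_setequal(names(lab), sampleIds(run$cohort$expr))
})

test_that("tied cluster polarity is rejected", {
  cohort <- simulateCohort(smallConfig(seed = 77L))
  constScores <- setNames(rep(1, ncol(cohort$expr)), sampleIds(cohort$expr))
  expect_error(
    discoverClasses(cohort$expr, cohort$truth$immuneGenes[1:40], constScores,
                    nRuns = 3, seed = 1, maxIter = 100),
    "tie")
})

test_that("discovery needs a minimum cohort size", {
  cohort <- simulateCohort(smallConfig(seed = 3L))
  tiny <- cohort$expr[, 1:10]
  sc <- setNames(runif(10), sampleIds(tiny))
  expect_error(discoverClasses(tiny, cohort$truth$immuneGenes[1:30], sc),
               ">= 20 samples")
})

test_that("refinement is a fixed point on clean labels and corrects flips", {
  run <- smallRun()
  cohort <- run$cohort
  truth2 <- ifelse(cohort$truth$class == "immune", "immune", "non-immune")
  sub <- alignGenes(cohort$expr, run$res$exemplars$selected)
  clean <- ClassLabels(names(truth2), unname(truth2))
  ref <- refineLabels(sub, clean, seed = 5)
  expect_identical(attr(ref, "flips"), 0L)
  expect_setequal(sampleIds(ref), sampleIds(clean))

  # pre-flip 5% of immune samples; most injected flips should be corrected
  corrected <- vapply(1:10, function(s) {
    set.seed(100 + s)
    immune <- names(truth2)[truth2 == "immune"]
    nFlip <- max(1, round(0.05 * length(immune)))
    flipped <- sample(immune, nFlip)
    noisy <- truth2
    noisy[flipped] <- "non-immune"
    ref2 <- refineLabels(sub, ClassLabels(names(noisy), unname(noisy)),
                         seed = s)
    mean(sampleLabels(ref2)[flipped] == "immune")
  }, numeric(1))
  expect_gte(mean(corrected), 0.6)
})

test_that("refinement is skipped for tiny classes", {
  x <- randomExprMatrix(30, 15, seed = 2)
  lab <- ClassLabels(sampleIds(x), c(rep("immune", 3), rep("non-immune", 12)))
  expect_warning(ref <- refineLabels(x, lab, seed = 1), "skipped")
  expect_identical(unname(sampleLabels(ref)), unname(sampleLabels(lab)))
})

test_that("classifier gene selection applies the DE contract", {
  set.seed(9)
  n <- 40
  immune <- paste0("i", 1:20); nonimmune <- paste0("n", 1:20)
  flat <- runif(n, 10, 11)
  up4x <- c(runif(20, 39, 41), runif(20, 9.5, 10.5))   # disjoint supports
  m <- rbind(flat = flat, de = up4x,
             noise = runif(n, 5, 50))
  colnames(m) <- c(immune, nonimmune)
  x <- ExpressionMatrix(m)
  lab <- ClassLabels(colnames(m), rep(c("immune", "non-immune"), each = 20))
  tab <- suppressWarnings(classifierGenes(x, lab, n = 150))
  expect_true("de" %in% tab$gene)
  expect_false("flat" %in% tab$gene)
  de <- tab[tab$gene == "de", ]
  expect_equal(de$log2FC, 2, tolerance = 0.1)
  # disjoint supports: rank-sum statistic is extreme, p_adj tiny
  expect_lt(de$pAdj, 1e-6)

  perm <- sample(ncol(m))
  tabPerm <- suppressWarnings(classifierGenes(x[, perm], lab, n = 150))
  expect_identical(tab$gene, tabPerm$gene)
  expect_equal(tab$log2FC, tabPerm$log2FC, tolerance = 1e-12)
})

test_that("classifier genes are drawn from the planted programs", {
  run <- smallRun()
  planted <- c(run$cohort$truth$immuneGenes, run$cohort$truth$stromalGenes)
  expect_gte(mean(run$res$classifier$gene %in% planted), 0.7)
})

test_that("transfer classification guards its preconditions", {
  run <- smallRun()
  imm <- run$cohort$signatures[["IMMUNE_TRUE"]]
  one <- run$cohort$expr[, 1, drop = FALSE]
  expect_error(transferClassify(one, run$res$classifier, imm), ">= 2 samples")
  expect_error(
    transferClassify(run$cohort$expr, paste0("ZZ", 1:50), imm),
    "coverage")
})

test_that("transfer reproduces discovery on the training cohort itself", {
  run <- smallRun()
  imm <- run$cohort$signatures[["IMMUNE_TRUE"]]
  agree <- vapply(1:3, function(s) {
    tv <- transferClassify(run$cohort$expr, run$res$classifier, imm,
                           nRuns = 10, seed = 200 + s, maxIter = 300,
                           tol = 1e-5)
    agreementRate(sampleLabels(tv), sampleLabels(run$res$twoLevel))
  }, numeric(1))
  expect_gte(mean(agree), 0.95)
})
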