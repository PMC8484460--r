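# Build a log-scale matrix whose gene-wise z profile on the template genes
# is exactly proportional to the template weights for sample 1.
perfectMatchMatrix <- function() {
  nG <- 30; nS <- 8
  v <- c(3, -1, -1, 2, 0.5, -2, 1, -2.5)      # shared cross-sample pattern
  w <- rep(c(1, -1), 5)
  m <- matrix(rnorm(nG * nS, 0, 1), nG, nS,
              dimnames = list(paste0("g", 1:nG), paste0("s", 1:nS)))
  for (i in 1:10) m[i, ] <- w[i] * v          # template genes g1..g10
  ExpressionMatrix(m, isLog = TRUE)
}

test_that("NTP distance hits 0 on a perfect template match", {
  set.seed(4)
  x <- perfectMatchMatrix()
  tpl <- NTPTemplate("T", paste0("g", 1:10), rep(c(1, -1), 5))
  res <- ntpClassify(x, tpl, nPerm = 200, seed = 2)
  # sample 1 has the largest pattern value: z-profile proportional to weights
  expect_equal(unname(res$distance["s1", "T"]), 0, tolerance = 1e-12)
  expect_equal(unname(res$p["s1", "T"]), 1 / 201, tolerance = 1e-12)
  expect_true(all(res$distance >= 0 & res$distance <= 2))
})

test_that("NTP distance is 1 for an orthogonal profile and 2 for the negation", {
  # z-profiles constructed directly on a log-scale matrix
  set.seed(5)
  x <- perfectMatchMatrix()
  tpl <- NTPTemplate("T", paste0("g", 1:10), rep(c(1, -1), 5))
  res <- ntpClassify(x, tpl, nPerm = 50, seed = 2)
  # the pattern v has zero-crossing samples; the most anti-correlated sample
  # (most negative v) has distance near 2
  expect_equal(unname(res$distance["s8", "T"]), 2, tolerance = 1e-12)
  # cosine distance of every column lies in [0,2] and argmin assigns
  expect_identical(unname(res$assigned["s1"]), "T")
})

test_that("cosine distance ignores positive rescaling of the profile", {
  z <- matrix(rnorm(50), 10, 5)
  w <- rep(c(1, -1), 5)
  d1 <- immunoclass:::.cosDistance(z, w)
  d2 <- immunoclass:::.cosDistance(z * 7, w)
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("two-template synthetic assignment is accurate", {
  set.seed(6)
  nS <- 200; nG <- 300
  classB <- seq_len(nS) > nS / 2
  mu <- matrix(1, nG, nS)
  mu[1:40, !classB] <- 4      # block A up in class A
  mu[41:80, classB] <- 4      # block B up in class B
  m <- mu * exp(matrix(rnorm(nG * nS, 0, 0.5), nG, nS))
  dimnames(m) <- list(paste0("g", 1:nG), paste0("s", 1:nS))
  x <- ExpressionMatrix(m)
  tA <- NTPTemplate("A", paste0("g", 1:40))
  tB <- NTPTemplate("B", paste0("g", 41:80))
  res <- ntpClassify(x, list(tA, tB), nPerm = 100, seed = 3)
  acc <- mean(res$assigned == ifelse(classB, "B", "A"))
  expect_gte(acc, 0.95)
})

test_that("resampling p-values are uniform under a label-free null", {
  set.seed(7)
  m <- matrix(rexp(400 * 200), 400, 200,
              dimnames = list(paste0("g", 1:400), paste0("s", 1:200)))
  x <- ExpressionMatrix(m)
  tpl <- NTPTemplate("T", paste0("g", sample(400, 30)))
  res <- ntpClassify(x, tpl, nPerm = 1000, seed = 9)
  frac <- mean(res$p[, "T"] < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("templates without overlap are skipped or fatal", {
  x <- randomExprMatrix(30, 6, seed = 3)
  good <- NTPTemplate("ok", geneIds(x)[1:8])
  bad <- NTPTemplate("gone", paste0("zz", 1:6))
  expect_warning(res <- ntpClassify(x, list(good, bad), nPerm = 20, seed = 1),
                 "skipped")
  expect_identical(colnames(res$distance), "ok")
  expect_error(suppressWarnings(ntpClassify(x, bad, nPerm = 20, seed = 1)),
               "all templates")
})

test_that("stromal split recovers planted subclasses and spares non-immune", {
  run <- smallRun()
  truth3 <- run$cohort$truth$subclass
  lab3 <- sampleLabels(run$res$threeLevel)
  expect_gte(agreementRate(lab3, truth3), 0.85)
  lab2 <- sampleLabels(run$res$twoLevel)
  expect_true(all(lab3[lab2 == "non-immune"] == "non-immune"))
  expect_true(all(lab3[lab2 == "immune"] %in%
                    c("immune-activated", "immune-suppressed")))
})

test_that("no stromal signal means everyone is immune-activated", {
  cohort <- simulateCohort(smallConfig(seed = 12L, noiseSigma = 0))
  truth <- cohort$truth
  # keep only activated + non-immune samples and flatten the stromal genes
  # across the immune class: no stromal evidence remains
  keep <- truth$subclass != "immune-suppressed"
  x <- cohort$expr[, keep]
  v <- exprValues(x)
  v[truth$stromalGenes, ] <- rep(rowMeans(v[truth$stromalGenes, ]),
                                 ncol(v))
  x <- ExpressionMatrix(v)
  lab2 <- ClassLabels(colnames(v),
                      ifelse(truth$class[colnames(v)] == "immune",
                             "immune", "non-immune"))
  tpl <- NTPTemplate("activated-stroma", truth$stromalGenes)
  lab3 <- splitSubclasses(x, lab2, tpl, nPerm = 50, seed = 2)
  sub <- sampleLabels(lab3)
  expect_true(all(sub[sampleLabels(lab2) == "immune"] == "immune-activated"))
})

test_that("suppression profile flags the stromal signature with the right sign", {
  run <- smallRun()
  cohort <- run$cohort
  sm <- scoreSignatures(cohort$expr, cohort$signatures, alpha = 0.25)
  prof <- suppressionProfile(sm, run$res$threeLevel)
  stromal <- prof[prof$feature == "STROMAL_TRUE", ]
  expect_lt(stromal$q, 0.05)
  expect_identical(stromal$direction, "up")

  # permuted labels: few features reach q < 0.05
  lab3 <- sampleLabels(run$res$threeLevel)
  fracs <- vapply(1:20, function(s) {
    set.seed(300 + s)
    perm <- setNames(sample(lab3), names(lab3))
    p <- suppressionProfile(sm, ClassLabels(names(perm), unname(perm)))
    mean(p$q < 0.05, na.rm = TRUE)
  }, numeric(1))
  expect_lte(mean(fracs), 0.05)

  expect_warning(
    p2 <- suppressionProfile(sm, run$res$threeLevel,
                             signatures = c("STROMAL_TRUE", "MISSING_SIG")),
    "not found")
  expect_true(is.na(p2$p[p2$feature == "MISSING_SIG"]))
})
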