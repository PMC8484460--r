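#' Simulate a cohort with planted immune structure
#'
#' Generates nonnegative expression from `kTrue` latent programs:
#' `X = (W0 H0) * exp(N(0, sigma^2))`. One program (the planted immune
#' factor) loads on a dedicated block of immune genes and dominates the
#' samples of the immune class; a stromal/TGF-beta-like program loads on a
#' second gene block and is additionally active in the immune-suppressed
#' subset of the immune class. Non-immune samples are dominated by one of
#' the remaining background programs. Overall survival is exponential with
#' subclass-specific hazards and independent exponential censoring;
#' disease-free survival is drawn the same way at 1.5x the baseline rate.
#' MSI status is sampled with subclass-dependent probabilities (0.40
#' activated, 0.15 suppressed, 0.05 non-immune).
#'
#' The emitted signature collection contains the true immune and stromal
#' gene sets plus five random decoy sets, so enrichment specificity is
#' testable without external signature files.
#'
#' @param config a [SimulationConfig-class]; `config@seed` drives all
#'   randomness, so equal configs give bit-identical cohorts.
#' @return list with elements `expr` ([ExpressionMatrix-class]), `clinical`
#'   ([ClinicalTable-class]), `signatures` ([SignatureCollection-class]) and
#'   `truth` (list: `class`, `subclass`, `dominantFactor`, `W0`, `H0`,
#'   `immuneGenes`, `stromalGenes`, `stromalFactorIndex`, `hazard`).
#' @export
simulateCohort <- function(config = SimulationConfig()) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  withSeed(config@seed, .simulateCohortImpl(config))
}

.simulateCohortImpl <- function(config) {
  nG <- config@nGenes; nS <- config@nSamples; K <- config@kTrue
  imm <- config@immuneFactorIndex
  stromal <- if (imm < K) imm + 1L else 1L

  genes <- sprintf("G%04d", seq_len(nG))
  samples <- sprintf("S%03d", seq_len(nS))
  immuneGenes <- genes[seq_len(config@immuneGeneCount)]
  stromalGenes <- genes[config@immuneGeneCount + seq_len(config@stromalGeneCount)]
  bgGenes <- setdiff(genes, c(immuneGenes, stromalGenes))
  bgFactors <- setdiff(seq_len(K), c(imm, stromal))

  # gene -> primary program map: immune block, stromal block, background
  # genes round-robin over the remaining factors
  program <- integer(nG)
  names(program) <- genes
  program[immuneGenes] <- imm
  program[stromalGenes] <- stromal
  program[bgGenes] <- rep_len(bgFactors, length(bgGenes))

  W0 <- matrix(stats::runif(nG * K, 0, 0.05), nG, K,
               dimnames = list(genes, paste0("F", seq_len(K))))
  W0[cbind(seq_len(nG), program)] <-
    config@loadingScale * stats::runif(nG, 0.8, 1.2)

  # per-sample class, subclass and dominant program; class sizes are fixed
  # at the configured fractions (rounded) with random membership, so every
  # cohort realizes the study composition exactly
  nImm <- round(nS * config@immuneFraction)
  immuneIdx <- sample.int(nS, nImm)
  isImmune <- seq_len(nS) %in% immuneIdx
  suppressedIdx <- sample(immuneIdx, round(nImm * config@suppressedFraction))
  isSuppressed <- seq_len(nS) %in% suppressedIdx
  subclass <- ifelse(!isImmune, "non-immune",
                     ifelse(isSuppressed, "immune-suppressed",
                            "immune-activated"))
  dominant <- integer(nS)
  dominant[isImmune] <- imm
  dominant[!isImmune] <- sample(bgFactors, sum(!isImmune), replace = TRUE)

  H0 <- matrix(stats::runif(K * nS, 0, 0.2), K, nS,
               dimnames = list(paste0("F", seq_len(K)), samples))
  # the stromal weight of suppressed samples is clearly secondary to their
  # immune weight, so the immune program stays each immune sample's dominant
  # factor (identifiable by argmax) while the stromal program remains
  # detectable within the immune class
  H0[cbind(dominant, seq_len(nS))] <- stats::runif(nS, 1.5, 2.5)
  H0[stromal, isSuppressed] <- stats::runif(sum(isSuppressed), 0.5, 1.0)

  M <- W0 %*% H0
  X <- if (config@noiseSigma > 0)
    M * exp(matrix(stats::rnorm(nG * nS, 0, config@noiseSigma), nG, nS))
  else M
  dimnames(X) <- list(genes, samples)

  hazardMult <- c("immune-activated" = config@hazardActivated,
                  "non-immune" = config@hazardNonImmune,
                  "immune-suppressed" = config@hazardSuppressed)
  rate <- config@baselineHazard * hazardMult[subclass]
  eventTime <- stats::rexp(nS, rate)
  cr <- config@censoringRate
  censRate <- if (cr > 0) mean(rate) * cr / (1 - cr) else 0
  censTime <- if (cr > 0) stats::rexp(nS, censRate) else rep(Inf, nS)
  osTime <- pmin(eventTime, censTime)
  osEvent <- as.numeric(eventTime <= censTime)

  dfsRate <- 1.5 * rate
  dfsEvent0 <- stats::rexp(nS, dfsRate)
  dfsCens <- if (cr > 0) stats::rexp(nS, 1.5 * censRate) else rep(Inf, nS)
  dfsTime <- pmin(dfsEvent0, dfsCens)
  dfsEvent <- as.numeric(dfsEvent0 <= dfsCens)

  msiProb <- c("immune-activated" = 0.40, "immune-suppressed" = 0.15,
               "non-immune" = 0.05)
  msi <- ifelse(stats::rbinom(nS, 1, msiProb[subclass]) == 1, "MSI", "MSS")

  clinical <- ClinicalTable(sampleIds = samples, osTime = osTime,
                            osEvent = osEvent, dfsTime = dfsTime,
                            dfsEvent = dfsEvent, msiStatus = msi)

  decoys <- lapply(1:5, function(i)
    GeneSet(paste0("DECOY_", i), sample(bgGenes, min(100, length(bgGenes)))))
  signatures <- SignatureCollection(c(
    list(GeneSet("IMMUNE_TRUE", immuneGenes, direction = "up"),
         GeneSet("STROMAL_TRUE", stromalGenes, direction = "up")),
    decoys))

  truth <- list(class = stats::setNames(ifelse(isImmune, "immune", "non-immune"),
                                        samples),
                subclass = stats::setNames(subclass, samples),
                dominantFactor = stats::setNames(dominant, samples),
                W0 = W0, H0 = H0,
                immuneGenes = immuneGenes, stromalGenes = stromalGenes,
                stromalFactorIndex = stromal,
                hazard = list(baseline = config@baselineHazard,
                              multipliers = hazardMult,
                              censoringRate = cr))
  list(expr = ExpressionMatrix(X), clinical = clinical,
       signatures = signatures, truth = truth)
}

#' Simulate an immunotherapy response cohort
#'
#' Draws a cohort from the same generative model as [simulateCohort()] and
#' assigns responder / non-responder labels by subclass: immune-activated
#' samples respond with probability `responderProbActivated`, all others
#' with `responderProbOther`.
#'
#' @param config a [SimulationConfig-class].
#' @param seed optional seed overriding `config@seed`.
#' @return list with `expr`, `response` (named character vector,
#'   `"responder"`/`"non-responder"`) and `truth`.
#' @export
simulateResponseCohort <- function(config = SimulationConfig(), seed = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  if (!is.null(seed)) config@seed <- as.integer(seed)
  cohort <- simulateCohort(config)
  resp <- withSeed(config@seed + 104729L, {
    p <- ifelse(cohort$truth$subclass == "immune-activated",
                config@responderProbActivated, config@responderProbOther)
    ifelse(stats::rbinom(length(p), 1, p) == 1, "responder", "non-responder")
  })
  names(resp) <- names(cohort$truth$subclass)
  list(expr = cohort$expr, response = resp, truth = cohort$truth)
}
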