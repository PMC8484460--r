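---
title: "Immune classification by NMF virtual microdissection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immune classification by NMF virtual microdissection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
decisions behind `immunoclass`, in the spirit of a methods supplement. The
README shows the user-facing workflow; here we explain *why* each stage is
built the way it is, what the synthetic data generator does and does not
emulate, and where the design was genuinely open.

## The generative picture

The package assumes bulk expression is an additive mixture of a small
number of nonnegative programs: `X ≈ W H` with gene loadings `W ≥ 0` and
sample weights `H ≥ 0`. Under this "virtual microdissection" view an
immune-infiltrated tumor is not a different tumor type but a sample whose
mixture weight on an immune program is large. Classification then proceeds
entirely on mixture structure:

* the **immune factor** is the program whose dominant samples score highest
  on an immune gene signature;
* the **immune class** consists of samples that cluster together on the
  immune factor's exemplar genes;
* the **immune-suppressed** subclass consists of immune-class samples whose
  profiles additionally align with an activated-stroma template.

Assumptions worth making explicit: expression must be on a linear,
nonnegative scale for the factorization (log data violate the additivity
the KL objective models); immune infiltration must be a *dominant* program
in the immune-class samples, not a trace signal; and the stromal program
must be expressed strongly enough within the immune class for a
cosine-based template match to see it above gene-level noise.

## Stage-by-stage choices

### ssGSEA scoring

Per sample, genes are ranked by expression in descending order (average
ranks for ties — ties are resolved identically on every platform, which
keeps scores deterministic), and the enrichment score is the running-sum
statistic accumulated over **all** rank positions, with hits weighted by
`rank^alpha`:

```
ES = sum_i [ P_hit(i) - P_miss(i) ]
```

The default `alpha = 0.25` follows the single-sample enrichment
literature. We use the summed variant rather than the maximum deviation:
the sum is smoother, and it is the variant conventionally associated with
single-sample scoring (the maximum-deviation statistic is used in the
subclass-mapping stage instead, where marker lists are short and a peak
statistic is appropriate; both statistics are implemented independently
and never share code). Internally the double sum collapses to a closed
form — a gene at rank `r` contributes to the `N - ceil(r) + 1` positions at
or after it — making scoring O(N log N) per sample while the tests verify
equivalence with a literal position-by-position implementation to 1e-9.

Scores depend only on within-sample ranks, so any monotone normalization
of a sample's values (TPM vs. counts, quantile scaling) leaves them
unchanged. Whether score matrices should be range-normalized before group
comparisons is not standardized in the literature; `scoreSignatures()`
exposes `normalize` as a flag (default off) and the group tests are rank
based, so the choice does not affect their p-values.

### NMF and consensus clustering

`nmfFactorize()` implements the classic multiplicative updates for the
generalized Kullback–Leibler divergence ("brunet" rules): random uniform
initialization from an explicit seed, `H` and `W` updated in alternation,
divergence recorded every iteration. The updates guarantee a non-increasing
loss, and the `NMFResult` validity method enforces that trace (tolerance
1e-8 relative) on every object. Iteration stops at a relative loss change
below `tol` (default 1e-6) or `maxIter` (default 2000). All-zero rows or
columns are dropped with a warning because the update rules divide by
marginal sums. A small additive epsilon (machine epsilon) guards the
elementwise divisions; it is orders of magnitude below the data scale in
any realistic matrix.

The microdissection rank default is `K = 10`. No automatic rank selection
is performed: `consensusNMF()` reports the consensus dispersion
(`mean(4 (C - 1/2)^2)`), which users can sweep over `k` themselves; rank
choice is reported, not decided. Before the full-rank run,
`madFilter()` keeps the top 5000 genes by median absolute deviation —
standard practice to drop uninformative flat genes; it is a no-op on
matrices already smaller than the cutoff.

Consensus clustering runs 30 factorizations from consecutive seeds,
averages dominant-factor co-assignment into a consensus matrix, and cuts
average-linkage hierarchical clustering of `1 - C`. Dominant factors are
argmax of `H` columns, ties broken toward the lowest index and flagged.

### The two-class discovery step and the posneg transform

The exemplar genes are one-sided: they are all *high* in the immune class.
On such a panel a rank-2 KL factorization of raw intensities does not
separate the classes — both factors latch onto the single shared profile
shape and the argmax assignment degenerates to intensity noise (we measured
consensus dispersion near 0.1 on cohorts where the classes are in truth
perfectly separable). `discoverClasses()` and `transferClassify()`
therefore log-transform the submatrix, standardize each gene, and stack the
positive and negative parts as separate nonnegative rows (the "posneg"
doubling used to feed signed data to NMF). One factor then anchors on
marker-high samples and the other on marker-low samples, and the consensus
becomes crisp. The consensus machinery itself is unchanged; the transform
is a preprocessing step of the two-class stage only.

Cluster polarity (which cluster is "immune") is decided by the higher
median immune enrichment score; an exact tie raises an error suggesting
more consensus runs rather than guessing.

### Label refinement

The refinement stage interprets the "MDS random forest" idea as: fit a
random forest (500 trees) to the exemplar-gene expression against the
preliminary labels; convert the forest's co-leaf proximity into a distance;
embed with classical MDS in 2 dimensions; reassign each sample to the
majority label of its 15 nearest embedded neighbors; iterate the
relabeling to a fixed point (at most 10 rounds). The forest and embedding
are fit once — the iteration only re-runs the cheap neighbor vote, since
refitting the forest on its own output risks label feedback and multiplies
cost tenfold. All knobs (`nTrees`, `kNeighbors`, `maxRounds`,
`minClassSize`) are arguments. Classes smaller than 10 samples skip
refinement with a warning: proximity estimates on a handful of samples are
too unstable to overrule the consensus labels.

### Differential expression for the transfer classifier

The classifier contract is: BH-adjusted `p_adj < 0.05` and `|log2FC| > 1`,
top 150 by absolute fold change. The test engine is the Wilcoxon rank-sum
on `log2(x + 1)` values with fold changes computed from linear-scale class
means (pseudocount 1). A negative-binomial count model would be the
canonical choice for raw RNA-seq counts, but the package must serve
simulated intensities and microarray-scale validation cohorts equally, and
the rank test is distribution-free across all of them; the selection
contract is unchanged. Whether a validation cohort should be re-clustered
on the *exemplar* genes or on the *DE-derived* genes is genuinely
ambiguous in the source material; both lists are available
(`exemplarScores()` and `classifierGenes()`), and `transferClassify()`
accepts either — the DE-derived list is the documented default.

### Nearest template prediction

Profiles are `log2(x+1)`-transformed and gene-wise z-standardized across
the samples being classified; distance is `1 - cosine` between a sample's
standardized template-gene profile and the template's ±1 weight vector.
Significance is by resampling `nPerm = 1000` random gene sets of equal
size from all genes, `p = (1 + #{d_rand <= d_obs}) / (1 + nPerm)`,
BH-adjusted across samples per template.

The stromal bifurcation runs NTP with the activated-stroma template
*against its negation*, which makes the argmin assignment a well-defined
two-class decision; a sample equidistant from both (no stromal evidence
whatsoever, e.g. constant stroma genes) stays immune-activated. Every
immune sample receives a subclass — the bifurcation is complete, matching
how the classification is meant to be consumed — while the per-sample
confidence flag (`q < 0.05` by default) is retained in the attached NTP
result for users who want to gate downstream analyses on it.

### Subclass mapping

Markers are ranked by signal-to-noise ratio on `log2(x+1)` values with the
GenePattern variance floor (`sigma >= max(0.2 |mu|, 0.2)`). Enrichment of
one cohort's markers in the other cohort's ranking uses the weighted
Kolmogorov–Smirnov maximum-deviation statistic; each direction gets a
permutation p-value by shuffling the respective cohort's labels, the two
directions are Fisher-combined (chi-square, 4 df), and the matrix is
Bonferroni-corrected across cells. One caveat is documented and tested:
the two directions share data, so Fisher's combination — which assumes
independence — is mildly anti-conservative under the null. The
per-direction permutation p-values are exact under label exchangeability
(verified empirically in the tests), and the Bonferroni correction absorbs
the combination's optimism in practice; conclusions should rest on the
corrected matrix, as they conventionally do for subclass mapping.

### Survival and contingency statistics

Kaplan–Meier estimates and the k-group log-rank test delegate to the
`survival` package (the test statistic is additionally verified against a
hand-computed observed-minus-expected oracle in the test suite).
Chi-square tests use no Yates continuity correction — the printed
class-composition tables are large enough that the correction is
immaterial, and the uncorrected statistic equals the squared two-proportion
z statistic, an identity the tests exercise. `method = "auto"` switches to
Fisher's exact test when any expected cell is below 5. For 2×2 tables the
sample odds ratio `ad/bc` is reported regardless of test, so the effect
estimate does not change when the test switches. Significance stars follow
the conventional mapping (ns > 0.05 through **** < 0.0001). Multivariate
survival modeling (Cox regression) is deliberately out of scope — it is an
off-the-shelf model users can fit on the emitted labels.

## The synthetic cohort generator

`simulateCohort()` is first-class, tested code, not a fixture. It plants:

* `kTrue = 10` latent programs over `nGenes = 2000` genes; 200 immune
  genes load on the immune program (index 7), 150 stromal genes on a
  stromal program, the rest round-robin over background programs;
* an immune class of 43% of `nSamples = 300`, of which 53% additionally
  carry the stromal program — the composition of the cohort the
  classification system was developed on. Class sizes are fixed at the
  configured fractions (rounded) with random membership, so every cohort
  realizes the study composition exactly rather than binomially;
* dominant sample weights U(1.5, 2.5) against background weights
  U(0, 0.2); the suppressed samples' stromal weight U(0.5, 1.0) is clearly
  secondary, so the immune program remains each immune sample's dominant
  factor (identifiable by argmax) while the stromal program stays
  detectable within the immune class;
* multiplicative lognormal noise (`noiseSigma = 0.3`), preserving
  nonnegativity and leaving within-sample ranks informative;
* exponential overall survival with hazard multipliers 0.6 (activated),
  1.0 (non-immune), 1.8 (suppressed) on a 1/1500 per-day baseline,
  independent exponential censoring targeting 20%; disease-free survival
  drawn analogously at 1.5× the rates; MSI status with subclass-dependent
  probabilities (0.40 / 0.15 / 0.05);
* a signature collection containing the true immune and stromal gene sets
  plus five random decoys, so enrichment specificity is testable;
* `simulateResponseCohort()` adds responder labels (probability 0.8 for
  immune-activated samples, 0.2 otherwise), standing in for an anti-PD-1
  treated reference cohort, which cannot be redistributed.

What the generator does **not** emulate: gene–gene correlation beyond the
low-rank structure, batch and platform effects, heavy-tailed count noise,
copy-number or mutation mechanisms, and any misspecification of the
signature (tests hand the generator's own gene sets to the scorer).
Passing tests therefore demonstrate that the pipeline recovers structure
*of the kind it assumes*; they do not certify performance on real cohorts,
where signature quality and mixture misspecification dominate.

## Problem sizes and runtime choices

The test suite and the acceptance script choose sizes that keep a full run
in the minutes range while preserving the study conditions where those are
stated: the pipeline-level checks use the default 2000 × 300 cohort across
10 seeds with the NMF capped at 300–500 iterations (tolerance 1e-5–1e-6;
convergence diagnostics show the relative loss change is below 3e-5 by
iteration 200 on these data), unit tests use a reduced 500 × 140 cohort
with 6 programs, immune-factor selection is swept over 20 seeds at
600 × 150, and permutation counts are 100–1000 depending on the
resolution a check needs. All of these are arguments, not constants.

## Known limitations

* KL-NMF is initialization-dependent; consensus clustering averages over
  restarts, but `W`/`H` themselves are reported from a single seed.
* The two-class stage relies on the posneg transform; a marker panel with
  genuinely two-sided structure would also work, but the package has only
  been validated on one-sided panels.
* NTP confidence (`q`) thresholds are reported, not used to withhold
  assignments; users wanting an "unclassified" category must gate on the
  flag themselves.
* The DE engine is a rank test, deliberately; users with raw counts and
  library-size artifacts should normalize before import.
* Fisher-combined subclass-mapping p-values are anti-conservative under
  dependence (see above); use the Bonferroni matrix.
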