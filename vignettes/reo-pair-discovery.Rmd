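---
title: "Discovering reversal gene-pair biomarkers from within-sample expression orderings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering reversal gene-pair biomarkers from within-sample expression orderings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reoPairs)
```

## The method

Absolute expression values travel badly between laboratories, platforms and
batches. The relative expression ordering (REO) of two genes inside one
sample — is gene *i* expressed above or below gene *j*? — survives any
strictly increasing per-sample transform, so a classifier built only on REOs
needs no renormalisation when it moves from RNA-seq to microarray to qPCR.
Within a tissue class these orderings tend to be stable; carcinogenesis
disturbs them. That asymmetry is the signal this package exploits.

The pipeline, for a training cohort with positive (cancer and
cancer-adjacent) and negative (normal, adenoma, IBD) samples:

1. **Consistent pairs.** For every unordered gene pair and each class, count
   the fraction of samples with each strict ordering. A pair is *consistent*
   in a class when one direction holds in strictly more than 70% of that
   class's samples (`detectConsistentPairs`). When several datasets or
   platforms are available, their consistent-pair sets are intersected:
   a pair survives only with the same direction everywhere, and keeps its
   weakest (minimum) frequency (`intersectConsistentSets`).
2. **Reversal pairs.** Pairs consistent in both classes with *opposite*
   directions (`detectReversalPairs`).
3. **Reversal degree.** Each reversal pair is scored by
   `avgR = sqrt(mean|R_i - R_j|_cancer * mean|R_i - R_j|_non-cancer)` —
   the geometric mean of the group-wise mean absolute within-sample rank
   differences (`scoreReversalPairs`). Pairs far apart in rank on both sides
   of the reversal score high. Ranks are ascending with average-rank ties.
4. **Forward selection.** With pairs ranked by descending `avgR`, every
   panel size `k = 1..m` is evaluated on the training samples under the
   half-voting rule, and the `k` maximising the geometric mean of
   sensitivity and specificity is kept (`forwardSelectPanel`).
5. **Half-voting classification.** A sample is called cancer when at least
   `ceiling(k/2)` panel pairs show the strict cancer-direction ordering
   `expression(gene_low) < expression(gene_high)` (`classifyMatrix`).

`discoverMarkerPanel()` chains steps 1–4.

```{r discover}
cohort <- simulateCohort(simulationConfig(seed = 11))
fit <- discoverMarkerPanel(cohort$matrix, cohort$annotation)
fit$panel
head(fit$per_k)
```

## Parameters that matter

* **Consistency threshold** (default `0.70`, a fraction of class samples).
  "More than 70%" is read strictly: a frequency of exactly 0.70 does not
  qualify. Raising the threshold shrinks the consistent sets monotonically.
  Below 0.5 both directions could qualify at once, so the constructor
  rejects such values.
* **Vote threshold.** Fixed at `ceiling(k/2)`: 3 of 6, 2 of 3, 1 of 1. With
  even `k`, exactly half the votes suffices.
* **Ties.** Equal values within a sample (common with zero-inflated FPKM)
  count toward *neither* direction in consistency frequencies — but stay in
  the denominator — and cast *no* vote in classification. This is
  conservative: tied zeros can never manufacture consistency or a cancer
  vote.
* **Tie-breaks.** Equal reversal degrees are ordered lexicographically by
  gene pair; equal training gmeans select the smallest `k` (the cheaper
  assay). Both choices exist purely to make results deterministic.

## Preprocessing rules

Microarray probes mapping to more than one gene are discarded before
anything else; multiple surviving probes for one gene are averaged
arithmetically per sample (`collapseProbes`); probes missing from the
mapping are dropped with a warning rather than an error, since a mapping
table *defines* the annotated universe. Raw counts convert to FPKM as
`count * 1e9 / (length_bp * librarySize)` with the library size taken as
the total count over the genes present in the matrix — the denominator's
universe is a documented choice, made so results are reproducible from the
shipped inputs alone (`countsToFPKM`). Since every downstream statistic is
rank-based, normalisation choices only matter through the length
correction. Cross-platform analyses must first restrict all matrices to a
common gene universe (`intersectGeneUniverse`).

Pooling versus intersecting datasets is left to the caller: similar-sized
datasets of one platform can be pooled into a single matrix, while
imbalanced ones are better passed separately to `discoverMarkerPanel()` /
`intersectConsistentSets()` so the larger cohort cannot dominate. No
automatic imbalance heuristic is applied.

qPCR cycle-threshold values *decrease* with abundance and must not be fed
to the classifier directly; `ctToRelativeExpression()` (`2^-(ct - ref)`)
is provided, and whether replicate wells are averaged on the Ct or the
linear scale is the caller's documented choice — the package does not guess
an assay scale.

## What the synthetic cohorts emulate

`simulateCohort()` generates the structure the method assumes, at desk
scale:

* **Background genes** draw independent log-normal values
  (`exp(N(mu_g, noise_sd))`, `mu_g ~ N(base_log_mean, base_log_sd)`), so no
  background pair carries a class-linked ordering.
* **Planted reversal pairs** show `gene_a < gene_b` with probability
  `fidelity_pos` in positive samples and `gene_a > gene_b` with probability
  `fidelity_neg` in negative samples. The ordering is imposed by swapping
  the pair's two sampled values when needed. Because both genes of a pair
  share one baseline mean, the swap preserves each gene's marginal
  distribution while controlling the REO fidelity exactly.
* **Planted-pair dispersion and spacing.** Forcing an ordering necessarily
  shifts each planted gene's class-conditional mean by about
  `0.56 * planted_noise_sd` on the log scale. A background gene whose
  baseline lands inside that window would form a spurious weak reversal with
  the planted gene. The defaults therefore give planted genes a tight
  dispersion (`planted_noise_sd = 0.1` against background `noise_sd = 0.5`)
  and space the pair baselines `planted_spacing = 1.5` log-units apart —
  marker genes occupying distinct abundance tiers with tightly regulated
  expression. This is a property of the generator's design, fixed a priori
  from the window calculation above.
* **Zero-inflation** (`tie_fraction = 0.02`) zeroes a small fraction of
  values after the orderings are imposed, exercising every tie-handling
  path the way real FPKM matrices do.
* **Platform effects.** `applyMonotoneDistortion()` passes each sample
  through its own strictly increasing transform (positive affine, power, or
  scaled log1p); `makePlatformViews()` partitions samples into disjoint
  "platforms" with partially overlapping gene universes (planted genes kept
  everywhere) and per-view distortions.
* **Strata labels** (stage, MSI status, primary site) are attached to
  cancer samples uniformly at random, purely so stratified evaluation is
  exercisable. They carry no biology.
* An optional **hub mode** shares one low gene across all pairs, mimicking
  published panels where one lncRNA anchors several pairs. Sequential
  swapping against the shared gene guarantees the desired ordering with
  probability *at least* the fidelity, not exactly equal to it.

What the generator does **not** emulate: gene–gene correlation networks,
the biological intermediacy of adenomas, MSI biology, library-size effects
on counts, or realistic platform-specific noise kinds. Passing tests on
these cohorts demonstrate that the algorithms are implemented correctly and
that the REO machinery is invariant to monotone distortion — they do not
certify clinical performance on real tissue.

## Numerical and degenerate-input choices

* All samples tied on a pair: direction frequencies are `(0, 0, 1)`; the
  Fisher reversal test has an empty table and returns an `NA` p-value with
  the tie count reported.
* A metric whose denominator is empty (no positives, or no negatives)
  returns `NA`, never a silent zero; the geometric mean is `NA` whenever
  either rate is.
* The geometric-mean identity `gmean^2 = sensitivity * specificity` holds
  to machine precision (one `sqrt` plus one squaring costs at most an ulp).
* Pair enumeration is exhaustive over `n(n-1)/2` pairs but processes one
  gene row against all later rows at a time, so memory stays `O(n * s)`;
  a 5,000-gene universe is feasible on a desktop.
* The two-sided Fisher p-value follows the standard convention of summing
  hypergeometric probabilities not exceeding the observed table's.

## Validation performed by the test suite

The suite builds every fixture in code and checks, among others:

* agreement of `detectConsistentPairs`, `reversalDegree`, the Fisher
  p-value and `forwardSelectPanel` with naive brute-force
  re-implementations on 100 randomised small instances each;
* bit-identical consistent sets, reversal pairs, reversal degrees, votes
  and calls after per-sample monotone distortions, across 20 seeded
  cohorts;
* recovery of planted reversal pairs on the reference cohort (200 genes,
  10 planted pairs, 30+30 samples, fidelity 0.9, 20 seeds) at >= 95%
  recall and precision with a background reversal rate below 1%;
* the full two-view pipeline — simulate, split, distort, discover,
  select, classify 20+20 held-out samples — reaching a held-out gmean of
  at least 0.9 at fidelity 0.95 over 10 seeds, with the selected `k`
  matching exhaustive search every time.

These cohort sizes keep the default test run under a minute on one core
while leaving the statistical margins comfortable.

## Known limitations

* Consistency detection applies no multiplicity control; with few samples
  per class, background pairs can clear the 70% threshold by chance.
  Intersecting across datasets or platforms is the intended mitigation.
* The classifier emits a hard call and an integer vote count; there is no
  probabilistic score or ROC machinery.
* Panel discovery requires both classes in the training data and at least
  one reversal pair; otherwise it stops with an error rather than
  degrading silently.
* Forward selection optimises on the training data only; selected panels
  should always be reported with held-out or external validation.
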