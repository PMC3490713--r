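---
title: "Methods: miRNA-target influence networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA-target influence networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its model, the choices
behind each default, and what the synthetic test bed does and does not
establish. Code shown is illustrative; the numerical claims the
package makes are the ones its test suite and `scripts/acceptance.R`
compute.

## The influence model

A miRNA lowers the abundance of its target mRNAs. Expression evidence
for a functional pair is therefore an *anticorrelated*, *informative*
relationship between the miRNA profile and the target profile — but a
target list predicted from seed-sequence complementarity alone admits
hundreds of candidates per miRNA, most of them silent in any given
tissue. The influence model scores a candidate pair `(miR, t)` by how
strongly the miRNA's signature propagates into the target's functional
neighborhood:

```
miRTI(miR, t) = Corrmir(miR, t) * W(miR, t) * max_k CorrFPI(t, k)
```

with mutual information `MI` as the dependence measure throughout:

* `Corrmir = MI(miR, t)` if the pair is sequence-predicted *and*
  Pearson-anticorrelated, else 0. The Pearson sign filter removes
  pairs whose high MI comes from positive co-variation, which
  repression cannot produce.
* `CorrFPI(t, k) = MI(t, k)` over the FPI edges incident to `t`; its
  maximum asks whether the target has at least one strongly
  co-expressed partner (i.e. sits in an active complex or pathway).
* `W = Σ_k MI(miR, k) · MI(k, t)` accumulates the miRNA's indirect
  footprint on the target through each partner.

The product form is deliberate: influence requires all three kinds of
evidence at once, and a structural zero in any channel (no sequence
support, no repression signature, an isolated target) annihilates the
score. Only the miRNA-target channel carries the negativity filter —
partner co-expression is evidence regardless of sign, so `W` and
`CorrFPI` use raw MI. A node is not its own FPI partner, so a target
whose only "neighborhood" is itself scores zero, and the maximum over
an empty partner set is zero.

### Mutual information estimation

MI needs a density estimate. The package discretizes each profile into
`n_bins = 8` equal-frequency bins (ties broken by stable rank order)
and sums `p(d,r)·log(p(d,r)/(p(d)p(r)))` over occupied cells of the
joint histogram, in nats by default (`log_base = "2"` gives bits).
Equal-frequency binning was chosen because

* it makes the estimate invariant under any strictly monotone
  transform of either profile — normalization choices upstream
  (log scale, quantile normalization) cannot change a score;
* `MI(x, x)` has the closed form of the binned marginal entropy, which
  anchors the estimator's scale and its tests;
* 8 bins against cohorts of ~100-150 samples keeps 12-18 observations
  per bin, enough that the independence bias `(B-1)²/(2n)` (~0.25
  nats at `n = 100`) stays well below the entropy ceiling
  `log 8 ≈ 2.08`.

The estimator is deterministic, so recomputation is bit-identical; the
builder computes each pairwise MI once (edge loop for `CorrFPI`,
bin-indicator matrix products in `mi_matrix()` for the miRNA × partner
block). Zero-variance profiles carry no information and yield `MI = 0`
rather than an error, so one flat probe cannot abort a cohort run;
the Pearson filter likewise treats a zero-variance profile as "no
correlation evidence" (score 0).

### Module extraction

Retention keeps pairs with `miRTI` strictly above the 75th percentile
(linear interpolation, type-7 quantile) of the *strictly positive*
scores. Zeros are excluded from the quantile population because they
are structural — counting annihilated pairs would let the threshold be
driven by the sparsity of the candidate relation rather than by the
strength of the retained evidence. The threshold is global rather than
per-miRNA, so miRNAs with uniformly weak evidence contribute nothing
rather than their "best" noise. Modules are connected components of
the retained miRNA-target edges plus the FPI edges among retained
targets, numbered by decreasing edge count with lexicographic
tie-breaks for determinism.

## Topology versus targeting

`topology_mirna_correlation()` reports, per protein, degree, local
clustering coefficient (`2·triangles/(k(k-1))`, 0 for degree < 2) and
betweenness, against the number of distinct targeting miRNAs. The
headline statistic is the signed per-protein Pearson correlation. An
alternative — correlating per-degree-bin means — mirrors how such
trends are usually drawn, and the binned means are indeed computed and
used by `autoplot()`; but with a realistic degree distribution only
one or two dozen bins clear a 5-protein floor, and a correlation over
so few points swings past ±0.3 routinely under a true null. The
per-protein statistic keeps the null tight, which is what makes the
randomization contrast meaningful.

The null model (`randomize_for_null()`) rewires the FPI graph by
double-edge swaps (every protein keeps its degree) and the bipartite
target relation by checkerboard swaps followed by a random permutation
of gene labels over the protein universe. The permutation step is the
important one: checkerboard swaps alone preserve each gene's targeting
count exactly, and since the degree-targeting correlation depends only
on per-node degrees and counts, it would survive any amount of
margin-preserving swapping *by construction*. Decoupling which protein
carries which targeting load — while preserving each miRNA's target
count exactly and the gene-side count distribution as a multiset — is
the weakest randomization that actually tests whether the trend
reflects joint structure.

## Activity centers

Per-gene differential-expression significance is `R = -log10(p)` from
a two-sided Welch t-test (pooled variance available via `var_equal`);
Welch is the default because group variances in tumor/normal contrasts
are rarely equal and the pooled test is anticonservative exactly when
the larger group has the smaller variance. Genes flat in both groups
get `p = 1`, `R = 0`; p-values are floored at the smallest positive
double so `R` stays finite. `-log10(p)` was chosen over `|t|` as the
significance scale because it is unbounded, monotone in evidence, and
makes the quadratic scaling of the activity score interpretable in
orders of magnitude.

The activity score of gene `i` with neighbors `d`,

```
ActivityScore(i) = mean_d(CorrFPI(i,d) · R(d)) * max_d(CorrFPI(i,d) · R(d))
```

is high when the neighborhood responds *on average* and contains at
least one strongly responding, strongly co-expressed partner. Genes
above the mean score are "principal regulators"; the mean is taken
over genes with at least one neighbor, since isolated genes' zeros are
structural. Regulators are split by their own p-value at
`p_thresh = 0.05`: differentially expressed centers are
transcriptional; high-scoring genes that are themselves quiet are
candidate post-translational regulators — their neighborhood moves
while they do not.

Stability (`activity_stability()`) re-estimates the DE significance on
80% stratified subsamples over 20 rounds (the co-expression network is
held fixed — it is not a function of the contrast) and reports the
mean pairwise squared correlation between round profiles. This is a
deliberate simplification of permutation-based resampling DE
machinery: what the stability question needs is only that the
significance profile be re-estimated on perturbed sample sets.

## Elastic-net influence regression

Patient expression over the gene universe is regressed on the miRTI
design matrix (genes × miRNAs, zeros off-target, all-zero columns
dropped). Each patient is fit independently — the model treats a
patient's profile as a linear combination of miRNA influence patterns,
and nothing couples patients — with `alpha = 0.5`: ridge alone
(`alpha = 0`) keeps every correlated miRNA in the model, lasso alone
(`alpha = 1`) picks one representative per correlated block, and
targets of co-regulated miRNAs *are* correlated by construction, so
the midpoint keeps groups while still sparsifying. The lambda path has
100 log-spaced values from the solver's `lambda_max` down to
`lambda_max · 1e-3`, chosen at minimum 10-fold cross-validated MSE.
The observations are genes, so CV folds are a seeded shuffle of genes,
shared across patients: results are identical whatever the patient
order. Predictors are standardized internally and coefficients
reported on the original scale, with an intercept — the reference
elastic-net solver's convention. Responses are used as-is; a constant
response short-circuits to the all-zero solution rather than erroring.
The activity-score profile is fit with the identical contract, one
pseudo-column named `"activity"`; positive coefficients mark miRNAs
whose influence pattern aligns with high neighborhood activity.

## Survival and classification evaluation

Risk stratification cuts a Ward-linkage tree on Euclidean distances at
two clusters. Correlation distance with average linkage is available,
but a risk signature in influence or expression features is a *mean
shift* in a few dimensions; per-sample correlation normalizes that
shift away and average linkage chains the diffuse remainder, while
Ward/Euclidean targets exactly compact mean-shifted groups. The
cluster with the larger mean feature value is labeled `"high"`. The
log-rank test and a one-covariate Cox fit give the chi-square,
p-value, and hazard ratio (with 95% CI); relabeling the groups inverts
the HR and leaves the chi-square unchanged, and splits where a group
has no events are flagged degenerate. Classification uses a linear
SVM, cost 1, under stratified k-fold CV with fold-internal z-scoring,
so reported accuracy is invariant to affine feature rescaling and
never sees test-fold statistics.

## The synthetic cohort

`simulate_dataset()` generates the study conditions every property
test runs on: 600 genes × 100 samples (30 normal / 60 primary / 10
metastatic), 50 miRNAs, 12 co-expression modules of 15 genes (dense
intra-module wiring, edge probability 0.6) on a preferential-
attachment background, 5 driver miRNAs each repressing one module
(`target = -1.0 · miR + 0.5 · latent + N(0, 0.5)`), drivers shifted by
class (0 / 0.8 / 1.2) and by +2 in a planted high-risk group, decoy
candidate targets drawn with probability ∝ degree^κ (κ = 1, ~12 per
miRNA) with *no* expression linkage, and exponential recurrence times
(baseline hazard 0.008/month, hazard ratio 2.8, uniform censoring on
[0, 120] months — roughly half the cohort censored). The decoy rate of
~12 per miRNA keeps the candidate relation realistically dominated by
non-functional pairs (~85-90%) while the planted pairs remain a
measurable fraction of the positive-score population.

What the generator emulates: negative miR-target correlation, neighbor
co-expression, class-linked differential expression, hub-biased
targeting, and risk-linked survival — every statistical structure the
pipeline's stages assume. What it does not: platform artifacts, batch
effects, probe-level noise, miRNA families with shared seeds,
non-Gaussian count noise, or realistic network sizes (a real FPI has
~10⁴ nodes; TargetScan relations are ~100× denser). Passing tests
therefore demonstrate that each stage recovers the structure it is
designed to detect at cohort-scale signal-to-noise — not that any
particular biological dataset will yield similar numbers.

Problem sizes in the tests and the acceptance script (20 simulation
seeds for recovery sweeps, 50-100 seeds for randomization and survival
nulls, 20 resampling rounds, full 100-patient regression on one seed)
were chosen to make Monte-Carlo fractions stable at the stated
thresholds while a complete run stays in the minutes range on a single
core.

## Degenerate inputs and numerical conventions

* Identifier matching is exact, case-sensitive string equality; no
  alias resolution.
* Missing expression cells are imputed with the row mean; rows over
  20% missing are dropped with a warning.
* Genes present in expression but absent from the FPI participate with
  zero neighbors (and thus zero `W`, `max CorrFPI`, activity score).
* Quantiles are type-7 (R's default, linear interpolation); the
  retention inequality is strict, so an all-equal score distribution
  retains nothing.
* All stochastic steps (randomization, subsampling, CV folds, the
  generator) take explicit integer seeds and restore the caller's RNG
  state; same seed, same bytes.

## Known limitations

* MI from 8-bin histograms is biased upward for independent pairs
  (~0.25 nats at n = 100); since every comparison in the pipeline is
  *relative* (quantile retention, maxima, products), the bias shifts
  scales, not rankings — but absolute miRTI values are not comparable
  across cohorts of different size.
* The influence score cannot distinguish direct repression from
  coherent co-regulation of miRNA and target by a third factor;
  the negative-correlation filter removes only the sign-inconsistent
  half of such confounding.
* Per-patient coefficients from a single-cohort elastic net are noisy;
  they rank miRNAs within a patient usefully, but clustering patients
  on raw coefficients is less reliable than clustering on expression
  (the acceptance script stratifies risk on miRNA profiles for this
  reason).
* The survival machinery assumes proportional hazards and
  non-informative censoring, as planted by the generator.
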