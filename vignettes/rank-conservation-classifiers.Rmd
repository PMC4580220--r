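---
title: "Rank-conservation transforms and robust subtype classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-conservation transforms and robust subtype classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diracnet)
```

## The model

`diracnet` classifies transcriptomic samples from the *relative* expression
of genes within curated gene sets (pathways), not from absolute expression
values. For a gene set with genes $g_1 < g_2 < \dots < g_k$ in canonical
(lexicographic) order, each sample is reduced to the binary vector of all
$k(k-1)/2$ pairwise comparisons

$$v_{ij} = [\,x(g_i) < x(g_j)\,], \qquad i < j,$$

which is unchanged by any strictly increasing transform of that sample's
values. For a class $C$, the **Rank Template** takes, per pair, the majority
comparison across the class's training samples:

$$RT_{ij} = [\,\hat P(g_i < g_j \mid C) > 0.5\,].$$

The **Rank Matching Score** of a sample against a template is the fraction
of agreeing pairs (one minus the normalized Hamming distance),
$RMS = \sum_{ij} [RT_{ij} = v_{ij}] / |RT|$, an exact rational in $[0,1]$.
The per-pair majority template provably maximizes the summed training RMS,
a property the test suite verifies by exhaustive enumeration on small sets.
When the template is itself the comparison vector of a strict total order
and the sample is tie-free, $RMS = (\tau + 1)/2$ with $\tau$ Kendall's rank
correlation between the sample and the template order — rank conservation
scoring is an affine image of Kendall's tau.

A pathway is **tightly regulated** in a class when in-class samples agree
strongly with their own template; the contrast
$\Delta = \overline{RMS}_{\text{in}} - \overline{RMS}_{\text{out}}$
(both under the in-class template) quantifies this: $\Delta > 0$ tight,
$\Delta < 0$ loose.

The **multi-network classifier** uses, for each retained gene set, the
**Rank Difference Score** $RDS = RMS_{C} - RMS_{\text{Rest}}$ as one
feature, and fits a linear one-vs-rest SVM per class on the resulting
samples-by-sets matrix. Two baselines put the rank transform in context:
the expression-value classifier (GEV; standardized absolute values of a
gene signature) and the within-sample-rank classifier (GEV-rank; each
sample's values replaced by ranks over the whole gene universe before
subsetting).

## Tunable parameters

* `min_fraction = 0.30`, `min_present = 5` (`filter_genesets()`): a set is
  kept when at least 30 % of its genes are measured; the absolute floor of
  5 avoids near-degenerate templates of one or two pairs, which the
  fraction rule alone would admit for small pathways.
* `cost = 1` (`svm_config()`): linear-kernel soft-margin cost. RDS features
  are bounded in $[-1, 1]$ and are deliberately *not* re-standardized; GEV
  features are standardized by training mean/SD because their scale is
  arbitrary. Linear kernels keep per-feature weights interpretable.
* `n_ocv = n_icv = 100` (`nested_cv_select()`): outer and inner
  cross-validation counts for signature selection; `top_k = 50` features
  enter the screen. `icv_aggregate` switches the per-size aggregation of
  inner sensitivities between the mean (default) and the median, two
  readings of the published procedure that are both recorded in the
  provenance.

## Numerical choices, ties and degenerate inputs

* Comparison bits use the strict inequality; ties yield 0. A pair
  probability of exactly 0.5 likewise yields a template bit of 0. This
  keeps the bit and template definitions consistent, at the price that
  tie-heavy (floored) data legitimately perturb rank features — surfaced,
  not hidden, by the tie-inducing preprocessing variant V5.
* Pair indexing is frozen at filtering time: pairs $(i, j)$, $i<j$, under
  lexicographic gene order, enumerated row-major, and serialized with
  templates so trained models are portable across cohorts.
* Templates are always estimated on training partitions only; every
  cross-validation layer re-estimates them inside its own training subset.
  Validation samples never touch screening, ranking, elimination or
  template estimation (audited via recorded provenance IDs).
* The moderated-t screen shrinks pooled per-feature variances toward a
  common prior, $\tilde s^2 = (d_0 s_0^2 + d\, s^2)/(d_0 + d)$, with
  $(d_0, s_0^2)$ from the method of moments on the log variances (trigamma
  inversion by Newton's method). When the moment estimate is non-finite
  (all variances essentially equal) the screen falls back to complete
  shrinkage and says so. Zero-variance features are excluded from the
  prior fit; an all-zero-variance matrix is an error.
* Feature ranking uses the single-feature global-test score statistic —
  the squared covariance between the scaled feature and the centered 0/1
  class indicator. Constant features score 0 and rank last. Ties anywhere
  break by feature name; size ties in backward elimination and list
  selection prefer the smaller signature (parsimony, determinism).
* Multiclass decisions take the argmax of the binary decision values;
  exact ties go to the lexicographically first class with a message. A
  two-class problem keeps a single binary sub-model.
* The location-scale batch correction standardizes each gene within each
  batch and restores the pooled moments, using population (denominator-n)
  moments so a second application is an exact fixed point. It is a
  deliberately simple adjustment — location and scale only, no
  empirical-Bayes pooling — sufficient to remove additive gene-wise shifts.

## What the synthetic generator emulates

`sim_config()` / `generate_dataset()` produce a multi-subtype cohort on the
log2 scale (emitted as raw intensities $2^{\text{latent}}$):

* **Tight sets**: a fixed latent gene ordering per (set, class), adjacent
  means `delta` apart, per-sample gaussian noise `sigma`. The default
  `delta/sigma = 3` makes adjacent-rank swaps uncommon (about 2 %) while
  distant pairs are essentially fixed, yielding in-class conservation
  around 0.99 (`conservation_index()` reports the realized value — RMS is
  an emergent statistic, so strength is parameterized by spacing and
  noise, not by a target score).
* **Loose sets**: the ordering is redrawn for every sample; any template
  estimated for such a class is arbitrary and the regulation contrast
  concentrates at 0.
* **Planted DE genes**: `n_planted` genes shifted by `planted_effect`
  (default 1.5 SD) in an assigned class — the analogue of a screened gene
  signature for the value-based baselines and the ground truth for the
  signature-selection experiments.
* **Defaults as study conditions**: 2 classes of 60 samples, 500
  background genes, one 20-gene set tight in class A and one 20-gene loose
  set (20 genes is a typical curated-pathway size), one third of each
  class held out as a second batch. The selection experiments use 2×100
  samples with 10 planted genes among 1000.

Perturbations reproduce the two robustness axes studied:

* `apply_preprocessing_variant()` V1–V6 emulate the downstream effect of
  common preprocessing pipelines: V1 log2; V2 log2 + quantile
  normalization; V3 per-sample affine rescaling with additive background
  up to half the sample median; V4 median-scaling; V5 background
  subtraction floored at a threshold (tie-inducing); V6 = V5 + quantile
  normalization. V1–V4 are strictly increasing per sample, so all
  rank-based features are *exactly* invariant; V5/V6 are not, and their
  perturbation is provably local to pairs involving floored genes.
* `inject_batch_effect()` offers a rank-breaking mechanism (`gene_shift`:
  per-batch-and-gene additive offsets, optionally relative to a reference
  batch) and a rank-preserving one (`sample_monotone`). The robustness
  suite uses shift SD 4 on the log2 scale as its strong-batch condition.

What passing tests on these data do **not** show: real microarray physics
(probe affinities, GC content, nonlinear saturation), correlated gene-gene
noise, annotation noise, or class imbalance beyond stratification. The
generator's batch shifts are independent across genes; real batch effects
are structured, so the magnitudes here calibrate qualitative regimes, not
real-data effect sizes.

## Design choices where the design was open

* **Pooled Rest templates.** The one-vs-rest extension estimates the Rest
  template from the pooled non-positive classes rather than averaging
  per-class templates; pooling matches the one-vs-rest framing and keeps
  the template a majority vote over actual samples.
* **Screening features for the pathway pipeline.** The nested-CV screen
  operates on the per-set RDS values computed from inner-training
  templates — the same feature the final SVM consumes — rather than on any
  per-gene surrogate.
* **ICV aggregation.** The published procedure can be read as 100 inner
  iterations or as 3 blocks with a median choice; both are implemented
  (`icv_aggregate`), the 100/100 mean reading being the default.
* **Probe collapsing order.** Probes are collapsed to genes (arithmetic
  mean) first; gene sets are intersected with the collapsed universe
  afterwards.
* **Unmapped probes are dropped**, not errored: annotation gaps are the
  norm, and the drop is logged.

## Problem sizes used by the shipped checks

The test-suite and acceptance-script experiments run at deliberately
desk-scale sizes chosen to estimate each quantity stably: 20 seeds for
contrast recovery and classifier accuracy, 10 for the batch-robustness
panel, 10–20 selection runs at `n_ocv = n_icv = 5`, exhaustive template
enumeration only for sets of ≤5 genes (≤1024 candidate templates). The
published procedure's 100/100 cross-validation defaults remain the package
defaults for real analyses.

## Known limitations

* Rank conservation is not immune to arbitrarily large gene-wise shifts:
  once batch offsets approach the tight set's total rank spacing
  (around SD 5–6 on the log2 scale for the default spacing of 1.5), the
  within-sample ordering itself is destroyed and the rank classifier can
  fail for a whole class at once. The robustness claims hold in the regime
  where shifts are large relative to the value-based signal but small
  relative to pathway rank spacing.
* Tie-heavy data (floored or saturated intensities) erode the strict
  comparison bits; V5/V6 quantify this.
* The significance machinery of the original differential-rank-conservation
  framework (permutation tests for differentially regulated networks) is
  out of scope; only the mean-RMS contrast is provided.
* `simple_batch_correct` removes location/scale differences only; it is a
  stand-in for heavier batch-correction machinery, not a replacement.

## A worked run

```{r example, eval = FALSE}
ds <- generate_dataset(sim_config(n_planted = 10), seed = 1)
logged <- apply_preprocessing_variant(ds$expr, "V1")
regulation_contrasts(logged, ds$truth$gene_sets)

report <- run_robustness_suite(seed = 1)
macro_average(report)
autoplot(report)
```
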