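---
title: "Screening process genes with forest importance and preranked enrichment"
author: "rfgsea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening process genes with forest importance and preranked enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Genes that participate in the same biological process tend to be mutually
predictive: within a gene regulatory network they form a tightly connected
subgraph. `rfgsea` turns that premise into a per-gene statistical test.
For each target gene $n$ in an $N \times S$ expression matrix (log2-scale
values, e.g. log2(TPM+1)), the package:

1. fits a bagged ensemble of unpruned regression trees with gene $n$ as the
   response and the other $N-1$ genes as predictors, examining all $N-1$
   predictors at every split;
2. scores every predictor with two variable-importance measures — the
   permutation score (%IncMSE: mean increase in out-of-bag MSE after
   permuting the predictor within each tree's out-of-bag samples, divided
   by its standard error across trees) and the impurity score
   (IncNodePurity: total split-wise reduction in residual sum of squares,
   divided by the number of trees);
3. ranks the $N-1$ predictors by each score in descending order and tests a
   *prior gene set* for the process (e.g. a curated database set with
   validated/screened/deduced confidence tiers) for enrichment at an
   extreme of each ranking, using the weighted Kolmogorov–Smirnov
   running-sum statistic with weight exponent 1 and a gene-label
   permutation null;
4. classifies gene $n$: positively enriched at significance $\alpha$ under
   the permutation score (`POSITIVE`), negatively enriched (`NEGATIVE` —
   permutation importance can be negative, and a prior set concentrated at
   the *bottom* of the ranking is evidence against membership), or neither;
   the impurity ranking contributes a plain significance flag, because only
   the permutation-score set is split by sign.

The final candidate list intersects three gene sets: permutation-score
positive, impurity significant, and the genes differentially expressed
between two consensus clusters of the samples:

$$\text{final} \;=\; \text{\%IncMSE-positive} \;\cap\; \text{IncNodePurity}
\;\cap\; \text{DEGs}.$$

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `n_trees` | 500 | trees per target-gene forest |
| `predictors_per_split` | `"all"` | bagged trees, the method's literal setting; an integer cap is available for genome-scale matrices |
| `min_samples_leaf` | 5 | minimum in-bag cases per leaf; bounds depth since no post-pruning is applied |
| `alpha` | 0.05 | per-gene enrichment threshold on the *raw* permutation p-value; BH-adjusted values are emitted alongside but not acted on |
| `n_perm` | 1000 | gene-label permutations per enrichment test |
| `k_range`, `n_resample`, `subsample_fraction` | 2–6, 1000, 0.8 | consensus clustering: k-means on 80% sample subsamples, 1000 rounds |
| `lfc_threshold`, `padj_threshold` | 1, 0.05 | DEG rule: \|log2FC\| > 1 and BH-adjusted p < 0.05 |

Seeding: a run-level root seed spawns one child seed per target gene by a
stable hash of the gene identifier, so per-gene results are independent of
iteration order, target subsetting, and worker count. Samples are put in
canonical (sorted-identifier) order before resampling, so results depend
only on which samples are present, never on column order.

## Numerical choices

* **Permutation importance** uses one permutation pass per tree per
  predictor (the standard estimator; repeats are configurable). The score
  is the mean/standard-error ratio; when the standard error is zero — as
  for a predictor never split on, whose per-tree increases are all zero —
  the raw mean is reported, which keeps "never used ⇒ exactly 0" exact.
* **Split ties**: candidate predictors are examined in random order per
  node. With collinear predictors the best splits induce identical
  partitions and exactly equal gains; a deterministic scan order would
  assign every such split to one fixed predictor and importance could not
  be shared between duplicates.
* **Enrichment score**: computed from the hit positions alone (between
  hits the running sum decays linearly, so extremes occur only adjacent to
  hits). Cumulative hit weights are normalised by their final cumulative
  sum and miss decrements use direct integer ratios, so a set occupying the
  top (bottom) of the ranking reaches exactly +1 (−1). A tie between the
  positive and negative extremes resolves positive and is reported
  (probability zero for continuous scores). Negative ranking scores enter
  hit weights through their absolute value; enrichment direction is carried
  by the sign of the score. The permutation p-value uses a +1 pseudo-count
  within the observed sign class, so it is conservative and never exactly
  zero; if the sign class is empty the normalised score is undefined
  (reported `NA`) and p = 1.
* **Moderated t**: per-gene pooled variances are shrunk toward a scaled
  inverse-chi-square prior fitted by the method of moments on the log
  scale (trigamma inversion); the statistic uses `df + d0` degrees of
  freedom. When the observed log-variance spread does not exceed the
  theoretical chi-square spread, the prior degrees of freedom are infinite
  and all genes share the common variance. `prior_df = 0` disables
  moderation (ordinary pooled t); a Welch option is available.
* **Zero-variance genes** are flagged at load, excluded as regression
  targets (their model is undefined), and retained as predictors so the
  universe $N$ stays stable. A gene with zero variance in both groups and
  equal means gets p = 1 in the DE stage by convention.

## Design choices that were genuinely open

* **Consensus k-means initialisation.** Each resampling round runs k-means
  from a *single random* start (configurable). Deterministic seeding or
  many restarts per round push every round to the same local optimum, so
  even structureless data yields a crisp consensus matrix — which would
  blind the very diagnostics (CDF area, delta area, within/between
  contrast) that consensus clustering exists to provide. Cluster
  instability on weak data is signal, not noise.
* **Cluster-number selection.** The advisory `chosen_k` is the smallest k
  whose successor adds less than `delta_threshold` relative CDF-area gain.
  The default 0.3 was calibrated on simulations with a known cluster
  number: at strong separation the relative gain one step past the true k
  falls to ≈0.25 or below while the gain up to the true k stays above 0.4.
  A `contrast_threshold` of 0.7 flags low-confidence choices: across
  structureless simulations the maximum within-minus-between consensus
  contrast stayed below ≈0.55, while genuinely clustered data approaches 1.
  Both curves are always written out; the end-to-end driver takes an
  explicit `k` (default 2), mirroring how the cluster number is chosen in
  practice by inspection.
* **Final labels** derive from average-linkage hierarchical clustering on
  `1 − consensus`, cut at k, renumbered by descending cluster size — the
  canonical consensus-clustering procedure; the log2 fold change is always
  cluster 1 (the larger) minus cluster 2.
* **Prior members as targets.** Genes of the prior set are themselves
  screened; each target is simply absent from its own predictor ranking,
  and the prior is intersected with the $N-1$ predictor universe before
  testing.
* **Multiplicity.** The per-gene screen thresholds the raw enrichment
  p-value at $\alpha$, as the method prescribes; BH-adjusted columns are
  emitted for reference only. The DE stage adjusts with BH across exactly
  the tested genes.

## What the synthetic generator emulates — and what it does not

`simulate_study()` plants a single-latent-factor module: module gene
$g$ measures $\beta_g z_s + \varepsilon$, with $z_s \sim N(\mu_{group}, 1)$,
$\beta_g \sim U(0.6, 1.2)$, and module residual noise at half the
background standard deviation so per-gene variances are comparable and the
module cannot be found by variance alone. The prior set mixes 20 true
module genes with 10 background decoys (tiers assigned round-robin),
mirroring the mixed confidence of curated databases. A group mean shift of
2 on the latent factor gives the clustering and DE stages their signal.
A single latent factor is the minimal structure that makes process genes
mutually predictive; it does not emulate graph-structured regulation,
count-level sampling noise, library-size effects, or correlated background
— so passing tests demonstrate the machinery works under the stated model,
not that the method overcomes every property of real cohorts.

Default study conditions are 200 genes × 120 samples with a 30-gene
module. Tests and the acceptance script run the forests at 100 trees and
the enrichment tests at 500 permutations for the end-to-end studies
(the per-target model is stable well below the 500-tree default at these
problem sizes); single-target checks use the stated 100-tree linear
simulations with 100 seeds, the permutation-null calibration uses 500
replicates of 1000 permutations, and consensus checks use 1000 resampling
rounds.

## Known limitations

* Screening all ~20,000 genes of a full cohort with all-predictors splits
  is computationally heavy by design; `predictors_per_split` and `workers`
  exist for that regime, and checkpointing lets interrupted screens resume.
* The negative-importance class (`NEGATIVE`) relies on the scaled
  permutation score; with `scale_importance = FALSE` the sign pattern is
  preserved but the variance normalisation differs.
* With strongly correlated informative predictors, importance is shared
  (each copy scores lower than it would alone) — an inherent property of
  permutation importance, visible in the duplicated-predictor tests.
* `chosen_k` is advisory; the delta-area elbow is a heuristic and is
  deliberately overridable everywhere a cluster number is consumed.
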