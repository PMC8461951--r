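---
title: "Mapping transcriptome signatures onto reference compendia by co-expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping transcriptome signatures onto reference compendia by co-expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A two-group transcriptome comparison — patients versus controls, active versus
inactive disease — yields a *signature*: the features (probe-sets or genes)
that differ between the groups, split into up- and downregulated lists. The
signature alone says little about *where* those transcriptional programs come
from. The approach implemented here interprets a signature by mapping it onto
a *reference compendium*: a collection of transcriptomes from labeled cell
states, such as bone-marrow differentiation stages, sorted blood cell subsets
(dendritic cells, neutrophils, monocyte subsets), G-CSF-mobilized leukocytes,
and in vitro stimulated monocytes. Signature genes that are co-expressed
across those reference states form clusters, and each cluster can be
attributed to the cell states in which its genes run highest — for example,
an upregulated cluster peaking in late granulopoiesis and blood neutrophils
reads as a neutrophil-like imprint on the queried cells, which in monocytes
is the expected footprint of a monocytopoiesis biased toward
granulocyte-monocyte progenitors.

## The procedure

`map_signature()` runs the chain:

1. **Harmonization.** The compendium, typically pooled from several datasets,
   is quantile-normalized: each sample's value at rank $r$ is replaced by the
   cross-sample mean of the $r$-th order statistics, so every sample has an
   identical value distribution. Ties within a sample all receive the mean of
   the mean-order-statistics of the positions they jointly occupy; this makes
   the transform well defined, symmetric in tied entries, and idempotent.
2. **Extraction.** The signature's features are pulled out of the compendium
   in signature order; features absent from the reference platform are
   reported, not silently dropped.
3. **Correlation.** Pearson correlation is computed between every pair of
   signature features across the reference samples, giving the gene–gene
   correlation matrix $R$. Zero-variance features are excluded with a report.
4. **Clustering.** $R$ is clustered by average linkage (UPGMA). Each feature
   is represented by its *row* of $R$ — its vector of correlations to all
   signature features — and Euclidean distance between rows feeds the
   agglomeration. This is the most direct reading of clustering "the
   gene-to-gene correlation" with Euclidean distance; the alternative of
   using $1 - r$ itself as the dissimilarity is available via
   `cluster_input = "one_minus_r"` and recovers the same planted structure in
   our synthetic checks.
5. **Cut.** Co-expression clusters in the literature are usually drawn by
   eye. Reproducibility needs a rule, so the cut is explicit: a fixed `k`, a
   height `h`, or (default) the `k` in 2–10 maximizing the mean silhouette
   width against the clustering distance.
6. **Display and attribution.** Each feature is z-scored across the reference
   samples and clipped to $[-2, +2]$ (the conventional relative-intensity
   scale: red $= +2$ above the feature mean, blue $= -2$ below). The
   attribution score of cluster $c$ for reference group $g$ is the mean over
   $c$'s features of the mean clipped z-score over $g$'s samples; per
   cluster, groups are ranked by score and the top group is reported.
   `render_ordered_heatmap()` draws the display matrix with rows in
   dendrogram leaf order and exports the ordered numbers so the figure is
   regenerable bit-exactly.

Up- and downregulated signatures are mapped in separate calls: their
co-expression structures answer different questions (what the queried cells
gained versus what they lost).

### The UPGMA engine

Average linkage defines the distance between clusters as the mean of all
pairwise member distances, maintained by the Lance–Williams update. The
engine is written in the package rather than delegated because reproducible
merge histories need a stated tie rule: when several pairs are tied at the
minimal distance, the pair whose clusters have the lexicographically smallest
(minimum-member, minimum-member) index merges first. The test suite holds the
engine to an independently coded brute-force $O(n^3)$ oracle — which
recomputes every cluster distance from the original matrix instead of
updating — over hundreds of random instances, and to `hclust`-compatible
downstream behavior (`cutree`, Newick export through `ape`).

## Differential-expression scoring

`score_two_group()` provides Welch's *t* (vectorized) or a Wilcoxon rank-sum
per feature, two-sided p, Benjamini–Hochberg adjustment (or none, matching a
raw p < 0.05 convention), and linear fold changes from group means (log2
input is exponentiated first). A zero-variance feature is scored 0 with
p = 1 rather than erroring, so flat control probes never abort a run. A
per-batch centering hook subtracts within-batch feature means before scoring,
for cohorts pooled across chips or sequencing runs; a full generalized linear
model with covariates is out of scope — that is what edgeR/limma are for.

`score_pairwise_concordance()` is a second, rank-based scorer: the fraction
of case × control sample pairs in which the case exceeds the control (ties
count half), mapped to $200(\text{fraction} - 0.5) \in [-100, 100]$, with a
user threshold on $|score|$ (default 100) defining membership. It is
invariant under strictly monotone transforms and echoes score-thresholding
conventions used with proprietary chip-analysis scores whose internals are
not public; it is an analogue of such scores, not a reconstruction.

## Synthetic data: what it emulates, and what it does not

Because patient-level expression data of this kind are typically not
deposited, every stage is validated on generated data with known truth:

- `generate_compendium()` plants block-structured marker expression: feature
  blocks elevated by `effect_log2` in chosen reference groups over a log2
  baseline, plus i.i.d. Gaussian noise. The default template
  (`default_compendium_spec()`) mirrors a 70-sample myeloid compendium —
  34 bone-marrow myelopoiesis samples, 15 blood subsets, 6 G-CSF-treated
  leukocyte samples, and 15 stimulated-monocyte samples (five stimulation
  conditions) — with four 40-feature marker blocks among 400 features.
- `generate_case_control()` plants a signature of per-feature log2 fold
  changes drawn as $N(\log_2 \text{mean\_fc}, \text{fc\_dispersion})$
  (negated for down-features). The default effect size is a mean fold change
  of 1.20 — deliberately small, the regime where single-gene differences are
  unconvincing but co-expression structure is still recoverable — at 25
  cases versus 10 controls. The truth table records both the structural
  (`fc_planted`) and the realized (`fc_realized`, recomputed from the
  emitted group means) fold change per feature.
- `generate_serum_markers()` produces sample × analyte tables with group
  shifts, normal or log-normal, for exercising the group-test stack.

Defaults that the emulated study design does not pin down are conventions,
chosen once: per-gene noise sd 0.25 (compendium) and 0.30 (case/control) on
the log2 scale, typical of microarray replicate spread; log2 baseline 7. The
demo dataset written by `make_demo()` uses noise sd 0.15 for its cohort so
that, at the small planted effect size, both signature directions survive
detection and the demo exercises mapping and enrichment end-to-end. All
generators draw from R's Mersenne-Twister through a seed-scoped wrapper, so
fixed seeds give bit-identical fixtures without touching global RNG state.

The generator does **not** simulate probe-level microarray physics, RNA-seq
read sampling (beyond an optional Poisson count transform,
`as_count_matrix()`), batch effects, or correlated noise. Passing the planted
-structure tests therefore shows the pipeline's inference is correct when
co-expression blocks exist and noise is independent; it does not show that
real compendia satisfy those assumptions.

### Effect-size fidelity and selection bias

With zero dispersion and zero noise the realized fold change of every
planted up-feature is exactly the target (1.20). With noise, the package
reports the mean *planted* fold change of the features the DE stage detects,
which stays at the target by construction under zero dispersion. The mean
*realized* (sample-estimate) fold change of detected features is larger —
detection selects features whose noisy estimate happens to be high (winner's
curse; at ~50% power and these sample sizes the inflation is roughly +0.06
to +0.09 on a 1.20 effect) — which is why the realized column should not be
used to summarize detected effects.

## Group statistics

- Mann-Whitney U: exact by full enumeration of labelings whenever both
  groups have ≤ 8 samples (valid under ties, which count half a pair; the
  permutation null of U is symmetric, so the two-sided p is the mass at
  least as far from $nm/2$ as observed); normal approximation with tie and
  continuity correction otherwise. Whether to prefer exact or asymptotic p
  at intermediate sizes is a matter of convention; the 8/8 switch point keeps
  enumeration ($\binom{16}{8} = 12{,}870$ labelings) instant.
- Kruskal-Wallis (tie-corrected, via `stats::kruskal.test`) with Dunn's
  post-hoc z-tests on mean ranks, Bonferroni-adjusted over all pairs by
  default (Holm and none available) — Bonferroni because the emulated
  analyses report conservative post tests without naming an adjustment.
- Welch's t with an optional Shapiro-Wilk gate (α = 0.05 per group) whose
  outcome is recorded alongside the result, making "t test after confirmed
  normality" an auditable statement.
- `pca_explained_variance()`: feature-centered PCA (no scaling by default,
  the common transcriptome convention; scaling behind a flag), explained
  -variance fractions, and a deterministic sign convention (each component's
  largest-magnitude loading is positive).
- `cluster_samples()` reuses the UPGMA engine on samples over z-scaled
  signature features.

## Over-representation

`overrepresentation()` is the hypergeometric upper tail
$P[X \ge k]$ for overlap $k$ between a query of size $n$ and a set of size
$K$ in a universe of size $N$, BH-adjusted across the collection. The
universe defaults to all annotated features of the platform, the standard
convention when none is declared. A ranked, running-sum enrichment statistic
is deliberately not implemented: signatures here are unordered gene lists,
for which overlap testing is the appropriate tool. `enrich_clusters()`
translates each co-expression cluster's probe-sets to genes (collapsing
many-to-one hits) before testing; clusters under 5 mapped genes are skipped
with a warning since a hypergeometric tail on a handful of genes is not
informative.

## Numerical choices and degenerate inputs

- Quantile normalization rejects non-finite cells by name; its tie rule is
  exact (no interpolation), making it idempotent to machine precision.
- Fold changes on log2 input are $2^{\bar{x}_1 - \bar{x}_2}$; on linear
  input, the ratio of means with a zero denominator giving `NA`.
- UPGMA tie-breaking is lowest-index-pair; merge heights are non-decreasing
  (average linkage is reducible), so `cutree` semantics are safe.
- `cut_clusters()` relabels clusters in order of first appearance, so labels
  are stable across runs.
- Pipeline TSVs are written with a fixed 15-significant-digit format;
  re-running an identical configuration reproduces byte-identical tables.

## Problem sizes used in the validation suite

The shipped tests and the acceptance script run at deliberately compact
scales chosen to mirror the emulated study design while staying quick: a
10,000 × 70 matrix for harmonization, 200 random instances of n ≤ 20 for the
clustering-engine oracle, the 70-sample/4-block compendium with a 160-feature
signature for planted-structure recovery, 10,000 null features at 25-vs-10
for calibration, and full enumeration sweeps (n, m ≤ 8; N ≤ 12) for the
exact statistics.

## Known limitations

- Attribution is a mean z-score readout, not a test; it ranks reference
  groups but attaches no uncertainty to the ranking.
- Quantile normalization is the only harmonization offered; systematic
  dataset effects that survive it (e.g. platform-specific probe behavior)
  are out of scope.
- The silhouette-based default cut favors compact, balanced clusters; for
  signatures dominated by one co-expression block it will still return
  k ≥ 2, splitting off small remainders (the demo's down-signature shows
  this). An explicit `k` is the right tool when the expected structure is
  known.
- The concordance score is an analogue of proprietary chip-scoring schemes,
  not a reimplementation of any of them.
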