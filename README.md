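# sigmap

Signature-to-reference co-expression mapping for transcriptome signatures.

## What it does, and for whom

A case/control transcriptome comparison yields a differential-expression
signature — lists of up- and downregulated features — but not an explanation.
`sigmap` is for researchers who want to read such signatures in terms of
**cell states**: it maps a signature onto a labeled reference compendium
(e.g. bone-marrow differentiation stages, sorted blood subsets, stimulated
monocytes), finds groups of signature genes that are co-expressed across
those references, and attributes each co-expression cluster to the reference
states in which its genes run highest. The motivating use case is monocyte
transcriptomics in chronic inflammatory disease, where an upregulated
cluster peaking in late granulopoiesis and blood neutrophils, together with
a downregulated dendritic-cell-like cluster, reads as a skew of
monocytopoiesis toward granulocyte-monocyte progenitors.

## The method

For a signature $S$ (one direction at a time) and a reference compendium
$Y \in \mathbb{R}^{p \times m}$ with sample group labels $g_1, \dots, g_m$:

1. **Quantile normalization** of $Y$: each sample's rank-$r$ value becomes
   the cross-sample mean of the $r$-th order statistics; ties receive the
   mean of their tied positions' mean order statistics.
2. **Gene–gene correlation**: $R_{ij} = \mathrm{cor}(y_i, y_j)$ (Pearson)
   across the $m$ reference samples, for $i, j \in S$.
3. **UPGMA clustering** of $R$: each feature is its row of $R$, Euclidean
   distance between rows, average linkage, deterministic lowest-index
   tie-breaking; the cut is an explicit $k$/height or maximum mean
   silhouette over $k \in [2, 10]$.
4. **Attribution**: with $Z$ the per-feature z-scored display matrix clipped
   to $[-2, +2]$, cluster $c$ scores
   $\mathrm{score}(c, g) = \frac{1}{|c|} \sum_{i \in c} \overline{Z_{i,\,\text{samples}(g)}}$
   for each reference group $g$; the top-ranked group names the cluster.

Around this core: Welch-t / rank-sum DE scoring with BH adjustment and a
pairwise-concordance score in $[-100, 100]$; hypergeometric over-representation
against GMT gene sets; PCA explained variance, sample clustering,
Mann-Whitney (exact by enumeration for groups of ≤ 8), Kruskal-Wallis with
Dunn post hoc; a synthetic-data generator that plants known co-expression
blocks and signatures; and a YAML-driven pipeline runner. See the vignette
(`vignettes/coexpression-mapping.Rmd`) for the full account.

## Worked example

```r
library(sigmap)

# a 70-sample reference compendium over four myeloid families, with four
# planted 40-feature marker blocks, and a 25-vs-10 cohort whose planted
# up-signature is drawn from blocks 1 (bone marrow) and 4 (stimulated)
comp <- generate_compendium(default_compendium_spec(seed = 1))
cc <- generate_case_control(case_control_spec(
  n_cases = 25, n_controls = 10, n_features = 400,
  signature_features = c(1:40, 121:160), direction = "up",
  mean_fc = 1.20, fc_dispersion = 0, noise_sd = 0.15, seed = 2))

de <- score_two_group(cc$exprs, cc$samples$group, case = "case", control = "control")
de
#> de_result [case_vs_control, welch_t]: 400 features, 77 significant (77 up, 0 down) at p_adj < 0.05

res <- map_signature(de$up, comp)
res
#> coexpression_result: 77 features, 2 clusters
#>   cluster 1 (40 features) -> BM_myelopoiesis (score 0.973)
#>   cluster 2 (37 features) -> stimulated_monocytes (score 1.780)

mk <- generate_serum_markers(c(axSpA = 18, HC = 9), c(axSpA = 0.35, HC = 0.35),
                             c(axSpA = 29, HC = 11), "lognormal",
                             analyte = "LBP", seed = 3)
two_group_test(mk$value, mk$group)
#> Mann-Whitney U: statistic = 296, p = 3.797e-05 (n = axSpA:29, HC:11)
```

Reading the output: at a planted mean fold change of only 1.20, 77 of the 80
planted features clear BH-adjusted significance; mapping them onto the
compendium splits them into two co-expression clusters that are attributed
exactly to the two reference families they were planted from (the
attribution score is a mean clipped z-score, so 1.78 means cluster-2 genes
sit ~1.8 SD above their compendium mean in stimulated monocytes). The
serum-marker test reproduces a strong two-group shift (p < 0.001) from a
two-fold planted difference.

The same chain runs from the shell over TSV/GMT/YAML inputs via the thin CLI
at `inst/cli/sigmap` (`sigmap demo`, `sigmap run --config run.yaml`,
`sigmap de`, `sigmap map`, `sigmap enrich`, `sigmap stats`), or in one call
with `make_demo()` + `run_pipeline()`.

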