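---
title: "Statistical models and design choices in preservstat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical models and design choices in preservstat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(preservstat)
```

## The problem

Comparative preservation studies in microbiome research split replicate
samples from several source materials (soils from different sites, feces
from different hosts) between two treatments — for example heat-assisted
desiccation versus freezing — and ask whether the treatment changes what a
sequencing workflow recovers. Two families of questions arise:

1. Does the treatment shift **scalar success metrics** (DNA yield, peak
   fragment size, read counts, OTU richness, Shannon diversity, contig
   statistics)?
2. Does the treatment distort the **inferred composition** — taxon
   proportions from amplicons, or gene/pathway proportions from
   metagenomes?

The obstacle to naive testing is that source materials differ from each
other far more than treatments do. preservstat therefore blocks every test
on material: the material is a stratum, never a nuisance to be averaged
away.

## The ratio-of-means statistic

For a metric $x$, material $m$ and treatments $(T_1, T_2)$ the package
computes

$$ r_m = \frac{\overline{x}_{m,T_1}}{\overline{x}_{m,T_2}}, \qquad
   R = \frac{1}{M}\sum_{m=1}^{M} r_m, $$

the ratio of treatment means within each material, averaged across the $M$
materials. Because the ratio is formed *before* averaging, material-level
baselines cancel; $R > 1$ indicates an overall positive effect of $T_1$,
$R < 1$ a negative one. `average_ratio()` implements the statistic;
`ratio_permutation_test()` attaches a significance level by comparing $R$
with its distribution under the stratified null model that reshuffles
treatment labels *within each material*, preserving group sizes. This null
keeps every between-material difference intact and destroys only the
metric–treatment association, which is exactly the effect under test.

Decisions worth knowing:

* **Averaging is arithmetic** by default. The plain mean of per-material
  ratios is the natural reading of "average of ratios"; a geometric option
  (`mean_type = "geometric"`) is provided because it is symmetric under
  swapping numerator and denominator. Note that swapping treatments inverts
  each $r_m$ but not, in general, the arithmetic $R$.
* **Two-sided extremity is measured on the log scale**: a null value $R'$
  counts as at least as extreme as the observed $R$ when
  $|\ln R'| \ge |\ln R|$. Ratios act multiplicatively, and the log scale
  treats a halving and a doubling as equally extreme. One-sided
  alternatives (`sidedness = "less"` / `"greater"`) compare raw ratios.
  Ties count as extreme (conservative), and all tie comparisons use a
  $10^{-12}$ relative tolerance so that mathematically tied statistics
  reached by different floating-point routes still register.
* **Exhaustive enumeration when feasible.** The number of distinct
  stratified assignments is $\prod_m \binom{n_m}{k_m}$
  (`count_stratified_assignments()`). At or below `exhaustive_limit`
  (default $10^5$) the test enumerates all of them and reports the exact
  tail fraction; the observed assignment is one of them, so $p > 0$. Above
  the limit it draws Monte-Carlo permutations and uses the
  $p = (1 + b)/(1 + N)$ estimator, which is also never zero.
* **Missing metric values** drop their sample (with a reported count)
  rather than failing: real metadata sheets are ragged, and each material
  only needs at least one value per treatment.

## Composition consistency between treatments

Within one material, `treatment_mean_proportions()` averages each feature's
proportion over the replicates of each treatment, and the consistency
statistic is the squared Pearson correlation of the *log* mean proportions,
$r^2 = \mathrm{cor}\left(\ln \bar p^{(1)}, \ln \bar p^{(2)}\right)^2$.
If the treatment had no effect and there were no sampling noise, every
feature would have equal means in both treatments — all points on the
diagonal, $r^2 = 1$. Replicate-level noise alone already pushes $r^2$ below
one, so the observed value is referred to a permutation null that
reshuffles treatment labels among the material's samples:
`consistency_permutation_test()` reports the probability that the null
produces an *even lower* $r^2$ (strict lower tail: a significantly low
$p$ means the treatments disagree more than replicate noise explains).

* **Abundance thresholding** (`threshold_filter()`) is applied first:
  features must reach `min_prop` in at least one compared sample
  (e.g. $10^{-4}$ for taxon tables, $10^{-5}$ for gene tables). The
  retained rows are *not* renormalized — they remain proportions of the
  full community. A `per_group_mean` mode thresholds group means instead,
  for gene-level analyses where means across replicates are the quantity
  of interest.
* **Zeros.** A feature can pass the threshold yet have mean zero in one
  treatment, where $\ln 0$ is undefined. The default policy
  (`half_min_pseudocount`) substitutes half the smallest nonzero mean of
  the compared pair; `drop` excludes such features and reports how many.
  Both are logged in the result because the choice is a genuine convention,
  not a consequence of the model.
* **Exhaustive p with a floor.** For $\binom{n}{k}$ assignments at or below
  `exhaustive_limit` the test enumerates the null exactly and reports
  $p = \max(\#\{r^2_{\text{null}} < r^2_{\text{obs}}\},\, 1) / n_{\text{assign}}$.
  The floor keeps $p$ positive at the resolution of the enumeration; a
  plain $+1$ correction was rejected because the label-swap complement of
  the observed assignment ties $r^2$ exactly, and on small designs the
  correction would push the exhaustive $p$ measurably above the
  Monte-Carlo limit. On very small designs (e.g. 3+3) the tie mass
  ($2/20$) still makes the strict lower-tail $p$ visibly conservative;
  at the 5+5 design the mass is $2/252$ and the null $p$ is uniform for
  practical purposes.

## Beta diversity: Bray-Curtis, PERMANOVA, MMDS

Pairwise community differences use the abundance-weighted Bray-Curtis
dissimilarity $BC(x, y) = \sum_i |x_i - y_i| \,/\, \sum_i (x_i + y_i)$
(`bray_curtis()`, `dissimilarity_matrix()`), which weighs each taxon by its
relative abundance and lives in $[0, 1]$.

`permanova()` implements one-way PERMANOVA directly from the distance
matrix: with $N$ samples in $a$ groups,
$SS_{\text{total}} = \tfrac1N \sum_{i<j} d_{ij}^2$,
$SS_{\text{within}} = \sum_g \tfrac{1}{n_g} \sum_{i<j \in g} d_{ij}^2$,
and the pseudo-F is
$F = \frac{SS_{\text{between}}/(a-1)}{SS_{\text{within}}/(N-a)}$.
Significance comes from unrestricted permutation of the group labels
within the analyzed subset (10000 by default), with exhaustive enumeration
of all distinct label arrangements on small designs. Alongside $F$, the
result carries $R^2 = SS_{\text{between}}/SS_{\text{total}}$ (variance
explained) and a standardized effect size
$\mathrm{SES} = (F_{\text{obs}} - \overline{F}_{\text{null}}) /
\mathrm{sd}(F_{\text{null}})$, which is comparable across analyses with
different group structures in a way raw $F$ is not. SES is defined here on
the raw $F$ scale; other definitions exist, so the formula is part of the
result's documentation. Only the one-factor design is supported — the
analyses this package targets test one factor at a time (treatment, or
material) on a chosen sample subset.

`mmds()` produces two-dimensional metric MDS embeddings by minimizing raw
stress $\sum_{i<j} (d_{ij} - \hat\delta_{ij})^2$ with SMACOF iterative
majorization, whose Guttman update never increases raw stress. The first
start is classical scaling (principal coordinates, used *only* as an
initialization); the remaining `n_restarts - 1` (default 9) starts are
random, guarding against local minima. The reported quantity is Kruskal
stress-1, $\sqrt{\sum (d - \hat\delta)^2 / \sum d^2}$ — the normalized
form conventionally printed on ordination plots. Exactly embeddable
configurations come back with stress at numerical zero; the regular
4-point simplex (all distances equal), which cannot embed in the plane,
converges to its known optimum (a square, raw stress $3 - 2\sqrt2$),
which the test suite uses as a self-consistency reference. Convergence is
declared at a relative raw-stress decrease below `tol` ($10^{-9}$) or
`max_iter` (1000) iterations.

## Gene-centric functional profiles

The metagenomic side consumes tabular outputs of an upstream pipeline
(read mapping filtered at MAPQ $\ge$ 30, gene prediction, HMM annotation at
E $\le 10^{-10}$ — all upstream, none reimplemented) and performs the
proportion arithmetic:

1. contig coverage = mapped reads / contig length; normalized to contig
   proportions summing to 1 per sample (`contig_proportions()`);
2. each predicted protein-coding gene (PCG) inherits its host contig's
   proportion; the PCG vector is renormalized to 1 (`pcg_proportions()`);
3. a KEGG ortholog (KO) sums the proportions of all PCGs mapped to it —
   *without* renormalization, so unannotated PCGs leave the KO total below
   1 (`ko_proportions()`);
4. KEGG level-C groups sum their member KOs, a KO in several groups
   counting in each, with eight non-functional catch-all groups ("brite
   hierarchies", "function unknown", ...) excluded case-insensitively
   (`kegg_group_proportions()`, `kegg_excluded_groups`).

A PCG with several KO hits contributes its full proportion to each KO by
default; since the convention is not universal, `multi_ko = "first"`
restricts to the first listed hit. The whole pipeline is scale-free in the
per-sample read counts — multiplying a sample's counts by any constant
changes nothing downstream — which the tests assert directly.

## The synthetic-data generator

Because the raw study data live in sequence archives, every test and the
acceptance script run on synthetic data whose generative structure matches
what the analyses assume:

* `simulate_metric_table()` draws
  $x = \text{baseline}_m \cdot \delta^{[t = T_1]} \cdot e^{\sigma z}$,
  $z \sim N(0,1)$: positive metrics, material-specific baselines
  (default log-spaced over a decade, materials genuinely differ),
  a multiplicative treatment effect $\delta$, log-normal replicate noise.
  With $\sigma = 0$ the average ratio recovers $\delta$ *exactly*; with
  $\delta = 1$ the null holds exactly. Default design 6 materials
  $\times$ (5+5), the scale of a realistic preservation study; default
  $\sigma = 0.2$, a moderate replicate scatter for positive lab metrics.
* `simulate_communities()` builds log-abundances per taxon
  (base $\sim N(0,1)$, material offsets $\sim N(0, \text{divergence})$,
  replicate noise $\sim N(0, 0.1)$), adds `effect_log_fc` to a fixed
  random subset of taxa in treated samples, and draws multinomial counts
  at the chosen depth. Fixing the affected-taxon subset per simulation
  (not per sample) makes the treatment a reproducible community-level
  signal.

What the generator does *not* emulate: PCR and chimera artifacts,
taxon-specific extraction biases, overdispersion beyond the log-normal
layer, and spatial sample heterogeneity. Passing tests therefore
demonstrate the statistical machinery is correct and calibrated under the
assumed generative structure — not that any particular field protocol is
unbiased.

## Calibration results the suite enforces

The test suite and `scripts/acceptance.R` recompute, from scratch:

* exact equality of all three permutation tests with brute-force
  enumeration oracles on small designs;
* type-I error within $[0.035, 0.065]$ at $\alpha = 0.05$ over 1000 null
  replicates, and p-value KS distance from uniform below 0.08 over 500
  replicates, for the ratio, consistency, and PERMANOVA tests;
* exact recovery of $\delta$ at $\sigma = 0$; pseudo-F exactly 1 under
  equidistance; MMDS stress $\le 10^{-6}$ on planar configurations;
* conservation: $SS_b + SS_w = SS_t$ (relative $10^{-10}$), contig/PCG
  proportions summing to 1 (absolute $10^{-9}$), Bray-Curtis within
  $[0, 1]$.

Problem sizes (40–100 taxa, depths $5\times10^3$–$10^5$, 200–1000
replicates, 199–999 permutations per replicate) were chosen as the
smallest at which these calibration statements are statistically sharp;
they are the package's own test conditions, and the same quantities scale
unchanged to full study-sized tables.

## Known limitations

* The ratio statistic presumes positive-valued metrics; metrics that can
  be legitimately zero or negative need transformation before testing.
* One factor per PERMANOVA; no crossed or nested designs, no dispersion
  test (a significant pseudo-F can reflect dispersion as well as location
  differences).
* The consistency test's strict lower-tail rule is conservative on very
  small designs because of exact label-swap ties (see above).
* MMDS is metric (Kruskal stress on raw dissimilarities), not non-metric;
  stress values depend on restarts only through local minima, and the
  default 10 restarts have been sufficient in all tested configurations.
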