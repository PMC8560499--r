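---
title: "Methods: integrating compartment bulk RNA-seq with single-nucleus profiles in diabetic kidney disease models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating compartment bulk RNA-seq with single-nucleus profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glomint)
```

## The scientific problem

Whole-cortex RNA-seq of a diseased kidney mixes glomerular signal with the
overwhelming tubular majority, so glomerular gene regulation in diabetic
kidney disease (DKD) is diluted or invisible in cortex data. The workflow
this package implements contrasts two compartments — laser-captured
glomeruli and whole cortex — across three phenotype groups (db/m controls,
uninephrectomized db/db mice with early DKD, "UNx", and the same model with
renin-driven hypertension and advanced DKD, "UNx-Renin"), and then maps the
resulting differentially expressed genes (DEGs) onto kidney cell types
derived from single-nucleus RNA-seq (snRNA-seq).

Because no public data accession accompanies the design, every stage is
driven by a synthetic-data generator with known ground truth; all claims
the test suite makes are claims about recovery of planted structure, not
about any real animal dataset.

## The synthetic cohort generator

`sim_config()` / `simulate_bulk()` / `simulate_sn()` produce a paired
cohort over one shared gene universe:

* **Counts.** Negative binomial throughout, parameterized by mean $\mu$ and
  dispersion $\alpha$ with $\mathrm{Var} = \mu + \alpha\mu^2$ (bulk default
  $\alpha = 0.1$, a typical within-group value for inbred mouse tissue).
  Nucleus counts are Poisson by default (`sn_dispersion = 0`), the common
  approximation for UMI-based single-cell counts.
* **Cell-type signatures.** Each of the 21 cell populations shares
  log-normal per-gene baselines (log-mean $\log 50$, log-sd 1). A fraction
  of genes (default 30%) are cell-type markers, multiplied `marker_fold`
  (default 4) in their own type. Markers are planted only on genes above a
  detectability floor (baseline above the ~16th percentile): curated marker
  genes are, by definition, measurably expressed, and below that floor a
  fourfold ratio is not resolvable at a few hundred nuclei per type.
* **Lineage programs.** A further 20% of genes are planted as pan-lineage
  programs (glomerular: podocyte-, mesangial-, endothelial-like types 1–3;
  tubular: the rest) at eightfold. These emulate slit-diaphragm versus
  solute-transport expression programs. They are what makes the
  compartments separate strongly in the joint PCA — single-type markers
  cannot, because each tubular type is only a few percent of cortex — and,
  being expression-tied within their lineage, they are never called
  cell-type-specific by the twofold rule.
* **Bulk means.** Compartment expectation = signature mixture under
  compartment weights: glomeruli concentrated on types 1–3, cortex
  dominated by the tubular types with a 1% glomerular admixture per
  glomerular type. Planted DEGs (default 10% of genes per non-reference
  group and compartment) multiply the (group, compartment) mean by a fold
  drawn from [2, 4] with random direction. Per-sample library factors are
  log-normal (sd 0.2) so size-factor estimation is non-trivial.
* **Mitochondrial content.** Mitochondrial genes (`mt-` prefix, flagged in
  the annotation) have zero expected expression in ordinary nuclei —
  nuclear RNA carries essentially no mitochondrial transcripts — while a
  planted 5% of nuclei carry a true 2% mitochondrial fraction. With ~5000
  counts per nucleus the empirical fraction then falls on the correct side
  of the 0.25% QC threshold with overwhelming probability, so the filter's
  retained set equals the generator's keep flag exactly.

What the generator does **not** emulate: batch effects beyond library size,
ambient RNA, doublets, UMI collisions, gene–gene correlation beyond the
planted block structure, and compartment-specific technical noise of
laser-capture microdissection. Passing tests therefore demonstrate correct
recovery of planted structure under a clean NB model, not robustness to
those artefacts.

With the default conditions, the joint PCA on the 500 most variable genes
puts roughly 78% of variance on PC1 (compartment) and ~4% on PC2, a
qualitative analogue of the dominant compartment separation the design
expects; the exact percentages depend on the planted fractions and folds.

## Differential expression

`nb_wald_test()` fits, per gene, the NB generalized linear model

$$\log \mu_{gj} = \log s_j + \beta_{g0} + \beta_{g1}\,x_j,$$

with $s_j$ the median-of-ratios size factor, $x_j$ the group indicator,
and tests $\beta_{g1}$ with a Wald $z = \hat\beta_{g1}/\mathrm{SE}$ against
the standard normal. Design choices:

* **Size factors** (`size_factors()`): the median over reference genes of
  the count-to-geometric-mean ratio, rescaled to geometric mean one.
  Reference genes are those expressed in every sample; when none exists a
  pseudo-reference over genes expressed in at least half the samples can be
  opted into (`pseudo_reference = TRUE`), announced via a message.
* **Dispersions** (`estimate_dispersions()`): per-gene method-of-moments
  on normalized counts pooled within groups,
  $\hat\alpha = \max\{0, (s^2 - \bar m)/\bar m^2\}$, then shrunk halfway
  (weight 0.5, configurable) toward a log-linear mean–dispersion trend and
  floored at $10^{-8}$. This is a light-weight stand-in for full
  empirical-Bayes machinery; at $n = 6$ per group the resulting Wald test
  is slightly anticonservative (pooled null rejection ~6.5% at nominal
  5%), which the acceptance band accounts for.
* **IRLS**: fits are vectorized across genes (the 2×2 normal equations are
  solved in closed form), capped at 50 iterations with linear predictors
  clamped to ±30; non-converged or degenerate fits (including genes
  all-zero in one group, whose group-effect MLE is unbounded) fall back to
  a moment-based $z$ with a message. All-zero genes are excluded and
  reported with $p = 1$.
* **Multiple testing**: Benjamini–Hochberg over tested genes
  (`bh_adjust()` wraps the standard step-up). Independent filtering
  excludes genes with mean normalized count below 1 (configurable) from
  the BH family; they are reported with adjusted $p = 1$. The DEG call is
  strict: adjusted $p < 0.05$.
* No log-fold-change shrinkage is applied; the DEG call uses adjusted p
  only, and raw MLE fold-changes are reported.

RPKM (`rpkm()`) is $10^9 c_{gj} / (L_g N_j)$ with $L_g$ the transcript
length in bp and $N_j$ the library size, used only for reporting
group-level means ± s.e.m. (sample-sd over $\sqrt n$; a singleton group
reports 0 with a warning).

## Gene-set perturbation

`gsa_run()` scores sets by the Stouffer statistic
$Z = \sum_g z_g / \sqrt n$ over members present in the tested universe.
Gene scores come from DE p-values, $z = \Phi^{-1}(1 - p/2)$ (computed in
the upper-tail form so values stay finite for $p$ near the 10^-300 floor),
signed by the fold-change in the *distinct-directional* mode and unsigned
in the *non-directional* mode. Non-directional set p-values are
upper-tail, directional ones two-sided; both modes are always reported
because the directionality class behind published perturbation rankings is
frequently unstated — coherently shifted sets surface in the directional
mode, sets regulated in mixed directions only in the non-directional one.
BH is applied across sets within one run; sets with fewer than 5 members
in the universe are dropped with a message, and the perturbation degree is
reported as $-\log_{10}(\text{adjusted } p)$.

## Single-nucleus integration

* **QC** (`filter_nuclei_mito()`): nuclei with mitochondrial fraction
  strictly above 0.25% are removed (a nucleus exactly at the threshold is
  retained); zero-count nuclei are removed with a message; an unflagged
  gene set degrades to a warning and a no-op.
* **Profiles** (`celltype_profiles()`): mean expression per cell type
  after scaling each nucleus to counts-per-10k (CP10K). The normalization
  is configurable (`norm = "raw"`) because a published specificity rule of
  this kind does not pin down the expression scale; CP10K is the default
  as the scale-free choice.
* **Specificity** (`assign_specific_genes()`): a gene is specific to a
  cell type when that type has the strictly highest profile value and the
  value is at least twofold (inclusive) the runner-up's. Exact top ties
  violate "the highest" and leave the gene unassigned. A zero runner-up
  with positive top expression is assigned with the ratio recorded as
  infinite — the rule is vacuously satisfied — and a minimum-expression
  floor (0.1 CP10K, configurable) suppresses noise-driven specificity in
  sparse data.
* **Superimposition** (`superimpose_degs()`): each specific gene is
  categorized as regulated in glomeruli only, cortex only, both, or
  neither, against the advanced-disease DEG sets; per-cell-type counts
  conserve totals by construction and are checked against set algebra in
  the tests.

## Compartment comparison

`top_variable_genes()` ranks genes by variance of $\log_2(x+1)$ on
size-factor-normalized counts (ties broken lexicographically);
`pca_samples()` takes the eigen-decomposition of the sample covariance of
the gene-centered log counts, reports eigenvalue percentages, and orients
every component so its largest-magnitude loading is positive, making score
signs reproducible across platforms. The log transform stabilizes count
heteroskedasticity before PCA; whether a published compartment PCA used
RPKM, normalized or transformed counts is typically unstated, so the input
matrix is the caller's choice. `venn_counts()` is exact set algebra.

## Problem sizes and determinism

The shipped analyses and checks run at desk scale, chosen so the full
suite completes in minutes on one core: 2000 genes, 6 samples per group
per compartment, 21 cell types at 100–200 nuclei per type, with 5–20
seeds for repeated-simulation checks. These sizes are stated in
`analysis/` and in the acceptance script and scale linearly. Every
stochastic stage draws from a single integer seed; reruns with the same
configuration are bit-identical, including all written TSVs (the manifest
records parameters, not timestamps).

## Known limitations

* The dispersion estimator is deliberately simple; at very small $n$ the
  Wald test inherits mild anticonservativeness (see above) and no outlier
  handling (Cook's-distance-style) is attempted.
* Only two-group contrasts with an intercept + indicator design are
  supported; no covariates.
* The specificity rule operates on pooled nuclei, not per-animal averages;
  both are defensible readings of the verbal rule, and the aggregation is
  kept configurable rather than asserted.
* Gene sets are an arbitrary GMT input; no pathway topology or hierarchy
  is used.
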