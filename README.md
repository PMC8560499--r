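# glomint

Integrative transcriptomics of kidney compartments in mouse models of
diabetic kidney disease (DKD): bulk differential expression in
laser-captured glomeruli versus whole cortex, Stouffer gene-set
perturbation scoring, and superimposition of compartment DEG sets onto
single-nucleus-derived cell types.

## What it does

Whole-cortex RNA-seq dilutes glomerular disease signal in the tubular
majority. This package implements the full comparison workflow for a
three-group design — db/m controls, uninephrectomized db/db mice (early
DKD, "UNx") and UNx with renin-driven hypertension (advanced DKD,
"UNx-Renin") — profiled in two compartments, and maps regulated genes onto
kidney cell populations:

* **Synthetic cohort generator** (`simulate_bulk()`, `simulate_sn()`):
  negative-binomial counts from cell-type signature mixtures with planted
  DEGs, cell-type markers, lineage programs, library-size variation and
  high-mitochondrial nuclei — all with exported ground truth, so every
  downstream stage is testable without data downloads.
* **Differential expression** (`nb_wald_test()`): per-gene NB GLM with log
  link and size-factor offset (median-of-ratios normalization,
  `size_factors()`), method-of-moments dispersions shrunk toward a
  mean–dispersion trend, Wald test, Benjamini–Hochberg adjustment
  (`bh_adjust()`), DEG call at adjusted p < 0.05 (`call_degs()`), RPKM
  (`rpkm()`).
* **Gene-set analysis** (`gsa_run()`): Stouffer statistic
  Z = Σz/√n over GMT collections (`read_gmt()`), non-directional and
  distinct-directional modes, −log10(adjusted p) perturbation degrees.
* **Single-nucleus integration** (`filter_nuclei_mito()`,
  `celltype_profiles()`, `assign_specific_genes()`,
  `superimpose_degs()`): >0.25% mitochondrial QC, counts-per-10k cell-type
  profiles, the twofold specificity rule (highest expression, at least
  twofold over the second-highest cell type), and categorization of
  specific genes as regulated in glomeruli, cortex, both or neither.
* **Compartment comparison** (`top_variable_genes()`, `pca_samples()`,
  `venn_counts()`, `gene_group_report()`): joint PCA of the 500 most
  variable genes with variance-explained percentages, DEG Venn partitions,
  group-level RPKM mean ± s.e.m. reports.
* **Pipeline** (`run_pipeline()`): chains all stages from one seeded
  configuration into a run directory of TSVs plus a parameter manifest;
  reruns are bit-identical.

## Worked example

The numbered scripts under `analysis/` run the whole study on a synthetic
cohort (2000 genes; 6 samples per group per compartment; 21 cell types,
100 nuclei each) and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_bulk_de.R
Rscript analysis/03_gene_sets.R
Rscript analysis/04_compartments.R
Rscript analysis/05_sn_integration.R
```

Output of a run with the default seed:

```
simulated 2000 genes x 18 bulk samples per compartment (3 groups x 6)
planted 800 DEG records; 600 cell-type markers
single-nucleus: 2100 nuclei, 113 above the 0.25% mito threshold

glomeruli  UNx       :  210 DEGs (padj < 0.05)
glomeruli  UNx-Renin :  211 DEGs (padj < 0.05)
cortex     UNx       :  224 DEGs (padj < 0.05)
cortex     UNx-Renin :  218 DEGs (padj < 0.05)
UNx: 187 glomeruli-only, 23 shared, 201 cortex-only

glomeruli  nondirectional  top set: planted_deg_glomeruli  -log10(padj) = 300.0

PC1 explains 79.1% of variance, PC2 4.1%
PC1 ranges: glomeruli [-30.3, -27.3], cortex [27.7, 30.7]

retained 1987 of 2100 nuclei after the >0.25% mito filter
600 genes assigned as cell-type-specific (twofold rule)
```

Reading: with 10% of genes planted as DEGs per contrast (200 of 2000), the
Wald test recovers essentially all of them in each compartment with few
false calls; the small DEG overlap between compartments (23/22 shared)
reflects that the DEG sets were planted independently per compartment —
the compartments genuinely regulate different genes. The planted DEG set
dominates the non-directional perturbation ranking (its adjusted p
underflows the 1e-300 floor). PC1 cleanly separates glomeruli from cortex
with no overlap in scores, and the mitochondrial filter removes exactly
the 113 planted high-mitochondrial nuclei.

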