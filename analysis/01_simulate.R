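#!/usr/bin/env Rscript
# Build the synthetic study cohort: paired glomerular/cortex bulk RNA-seq
# for db/m, UNx and UNx-Renin mice, plus a labelled single-nucleus matrix
# over 21 kidney cell populations, with full ground truth.

library(glomint)

seed <- as.integer(Sys.getenv("GLOMINT_SEED", "1"))
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(n_genes = 2000, n_per_group = 6, n_celltypes = 21,
                  n_nuclei_per_type = 100, seed = seed)
bulk <- simulate_bulk(cfg)
sn <- simulate_sn(cfg)

write_counts_tsv(bulk$counts_glomeruli, file.path(out, "counts_glomeruli.tsv"))
write_counts_tsv(bulk$counts_cortex, file.path(out, "counts_cortex.tsv"))
write_sample_table(bulk$sample_table, file.path(out, "samples.tsv"))
write_gene_annotation(bulk$gene_annotation, file.path(out, "genes.tsv"))
write_mtx(sn$counts, file.path(out, "sn"), is_mito = sn$gene_annotation$is_mito)
write_labels(sn$labels, file.path(out, "sn", "labels.tsv"))
write_truth(bulk$truth, file.path(out, "truth_bulk"))
write_truth(sn$truth, file.path(out, "truth_sn"))

qc <- sn$truth$nucleus_qc_table
cat(sprintf(
  "simulated %d genes x %d bulk samples per compartment (%d groups x %d)\n",
  cfg$n_genes, nrow(bulk$sample_table) / 2, length(cfg$groups),
  cfg$n_per_group))
cat(sprintf("planted %d DEG records; %d cell-type markers\n",
            nrow(bulk$truth$deg_table), nrow(bulk$truth$marker_table)))
cat(sprintf("single-nucleus: %d nuclei, %d above the 0.25%% mito threshold\n",
            nrow(qc), sum(!qc$keep)))
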