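#!/usr/bin/env Rscript
# Joint PCA of both compartments on the 500 most variable genes, and the
# group-level RPKM report for the strongest glomerular DEGs.

library(glomint)

data_dir <- "results/data"
counts_g <- read_counts_tsv(file.path(data_dir, "counts_glomeruli.tsv"))
counts_c <- read_counts_tsv(file.path(data_dir, "counts_cortex.tsv"))
samples <- read_sample_table(file.path(data_dir, "samples.tsv"))
ann <- read_gene_annotation(file.path(data_dir, "genes.tsv"))

joint <- cbind(counts_g, counts_c)
normed <- sweep(joint, 2, size_factors(joint, pseudo_reference = TRUE), "/")
hvg <- top_variable_genes(normed, 500)
pca <- pca_samples(normed, hvg)

cat(sprintf("PC1 explains %.1f%% of variance, PC2 %.1f%%\n",
            pca$var_explained[1], pca$var_explained[2]))
comp <- samples$compartment[match(rownames(pca$scores), samples$sample_id)]
cat(sprintf("PC1 ranges: glomeruli [%.1f, %.1f], cortex [%.1f, %.1f]\n",
            min(pca$scores[comp == "glomeruli", 1]),
            max(pca$scores[comp == "glomeruli", 1]),
            min(pca$scores[comp == "cortex", 1]),
            max(pca$scores[comp == "cortex", 1])))

utils::write.table(
  data.frame(sample_id = rownames(pca$scores), pca$scores[, 1:5],
             check.names = FALSE),
  "results/pca_scores.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(
  data.frame(pc = seq_along(pca$var_explained),
             var_explained_pct = pca$var_explained),
  "results/pca_variance.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

de <- utils::read.delim("results/de_glomeruli_UNxRenin.tsv")
top_genes <- head(de$gene_id[order(de$padj)], 6)
rp <- rpkm(joint, setNames(ann$length_bp, ann$gene_id))
report <- gene_group_report(rp, samples, top_genes)
utils::write.table(report, "results/gene_report.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("top glomerular DEGs (mean RPKM by group, glomeruli):\n")
print(format(subset(report, compartment == "glomeruli",
                    c(gene_id, group, mean_rpkm, sem_rpkm)), digits = 3),
      row.names = FALSE)

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  df <- data.frame(PC1 = pca$scores[, 1], PC2 = pca$scores[, 2],
                   compartment = comp,
                   group = samples$group[match(rownames(pca$scores),
                                               samples$sample_id)])
  p <- ggplot(df, aes(PC1, PC2, colour = compartment, shape = group)) +
    geom_point(size = 2.5) +
    labs(x = sprintf("PC1 (%.0f%%)", pca$var_explained[1]),
         y = sprintf("PC2 (%.0f%%)", pca$var_explained[2])) +
    theme_bw()
  dir.create("results/figures", showWarnings = FALSE)
  ggsave("results/figures/pca.pdf", p, width = 5, height = 4)
}
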