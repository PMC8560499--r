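#!/usr/bin/env Rscript
# Stouffer gene-set perturbation scoring of the advanced-disease contrast
# (UNx-Renin vs db/m) in each compartment, in both directionality modes.
# The collection holds random background sets plus one planted set per
# compartment built from the ground-truth DEG table.

library(glomint)

seed <- as.integer(Sys.getenv("GLOMINT_SEED", "1"))
data_dir <- "results/data"
truth <- read_truth(file.path(data_dir, "truth_bulk"))
genes <- read_gene_annotation(file.path(data_dir, "genes.tsv"))$gene_id

planted <- list()
for (comp in c("glomeruli", "cortex")) {
  ids <- unique(truth$deg_table$gene_id[
    truth$deg_table$compartment == comp &
      truth$deg_table$contrast == "UNx-Renin_vs_db/m"])
  planted[[paste0("planted_deg_", comp)]] <- ids
}
collection <- make_gene_sets(genes, n_sets = 50, planted = planted,
                             seed = seed)
write_gmt(collection, file.path(data_dir, "gene_sets.gmt"))

for (comp in c("glomeruli", "cortex")) {
  de <- utils::read.delim(file.path("results",
                                    paste0("de_", comp, "_UNxRenin.tsv")))
  for (mode in c("nondirectional", "directional")) {
    g <- gsa_run(de, collection, mode = mode)
    utils::write.table(g, file.path("results",
                                    paste0("gsa_", comp, "_", mode, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    top <- g[1, ]
    cat(sprintf("%-10s %-15s top set: %-22s -log10(padj) = %.1f\n",
                comp, mode, top$set, top$neglog10_padj))
  }
}
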