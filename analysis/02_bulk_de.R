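#!/usr/bin/env Rscript
# Differential expression per compartment: NB Wald test of UNx and
# UNx-Renin against db/m controls, DEG totals and the Venn partition of
# glomerular versus cortical DEG sets.

library(glomint)

data_dir <- "results/data"
out <- "results"
counts <- list(glomeruli = read_counts_tsv(file.path(data_dir, "counts_glomeruli.tsv")),
               cortex = read_counts_tsv(file.path(data_dir, "counts_cortex.tsv")))
samples <- read_sample_table(file.path(data_dir, "samples.tsv"))

degs <- list()
for (comp in names(counts)) {
  st <- samples[samples$compartment == comp, ]
  for (grp in c("UNx", "UNx-Renin")) {
    res <- nb_wald_test(counts[[comp]], st, c(grp, "db/m"))
    key <- paste0(comp, "_", gsub("[^A-Za-z0-9]+", "", grp))
    utils::write.table(res, file.path(out, paste0("de_", key, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    degs[[key]] <- call_degs(res, 0.05)
    cat(sprintf("%-10s %-10s: %4d DEGs (padj < 0.05)\n", comp, grp,
                length(degs[[key]])))
  }
}

for (grp in c("UNx", "UNxRenin")) {
  v <- venn_counts(degs[[paste0("glomeruli_", grp)]],
                   degs[[paste0("cortex_", grp)]])
  cat(sprintf("%s: %d glomeruli-only, %d shared, %d cortex-only\n", grp,
              v$counts[["only_a"]], v$counts[["shared"]],
              v$counts[["only_b"]]))
}

writeLines(unlist(lapply(names(degs), function(k) {
  paste(k, paste(degs[[k]], collapse = ","), sep = "\t")
})), file.path(out, "deg_sets.tsv"))
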