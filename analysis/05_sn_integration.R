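#!/usr/bin/env Rscript
# Single-nucleus integration: mitochondrial QC, per-cell-type profiles,
# the twofold specificity rule, and superimposition of the UNx-Renin vs
# db/m DEG sets from both compartments onto cell types.

library(glomint)

data_dir <- "results/data"
sn <- read_mtx(file.path(data_dir, "sn", "matrix.mtx"),
               file.path(data_dir, "sn", "features.tsv"),
               file.path(data_dir, "sn", "barcodes.tsv"))
labels <- read_labels(file.path(data_dir, "sn", "labels.tsv"))

filt <- filter_nuclei_mito(sn, attr(sn, "is_mito"))
cat(sprintf("retained %d of %d nuclei after the >0.25%% mito filter\n",
            ncol(filt), ncol(sn)))

labels <- labels[labels$barcode %in% colnames(filt), ]
tab <- cell_counts_per_type(labels)
utils::write.table(data.frame(cell_type = rownames(tab), tab,
                              check.names = FALSE),
                   "results/cell_counts.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

profiles <- celltype_profiles(filt, labels)
spec <- assign_specific_genes(profiles)
cat(sprintf("%d genes assigned as cell-type-specific (twofold rule)\n",
            sum(!is.na(spec$cell_type))))
utils::write.table(spec, "results/specificity_map.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

de_g <- utils::read.delim("results/de_glomeruli_UNxRenin.tsv")
de_c <- utils::read.delim("results/de_cortex_UNxRenin.tsv")
summary <- superimpose_degs(spec, call_degs(de_g), call_degs(de_c))
utils::write.table(summary, "results/integration_summary.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat("cell types with most regulated specific genes:\n")
ord <- order(-(summary$glomeruli + summary$cortex + summary$both))
print(head(summary[ord, ], 5), row.names = FALSE)
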