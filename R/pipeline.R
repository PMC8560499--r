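#' Pipeline configuration
#'
#' Collects the stage parameters of the end-to-end synthetic run with the
#' defaults the pipeline is anchored to: DEG call at adjusted p < 0.05,
#' twofold specificity, 0.25% mitochondrial QC threshold, 500 top-variable
#' genes for the joint PCA, and a minimum gene-set size of 5.
#'
#' @param sim a [sim_config()] for the synthetic cohort.
#' @param alpha DEG significance level (strict `<` on adjusted p).
#' @param fold specificity fold threshold.
#' @param mito_threshold mitochondrial QC threshold (fraction).
#' @param top_n genes for the PCA.
#' @param min_set_size minimum gene-set size.
#' @param min_expr specificity minimum-expression floor (counts-per-10k).
#' @param profile_norm `"cp10k"` or `"raw"` cell-type profile normalization.
#' @param n_gene_sets,gene_set_size_range random gene-set collection used
#'   for the Stouffer stage (plus one planted DEG set per compartment).
#' @param report_genes number of top DEGs included in the RPKM group report.
#' @param seed integer seed for every stochastic stage.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(seed = seed),
                            alpha = 0.05, fold = 2,
                            mito_threshold = 0.0025, top_n = 500,
                            min_set_size = 5, min_expr = 0.1,
                            profile_norm = "cp10k",
                            n_gene_sets = 50,
                            gene_set_size_range = c(10, 50),
                            report_genes = 6,
                            seed = 1L) {
  stopifnot(alpha >= 0, alpha <= 1, fold >= 1, mito_threshold >= 0,
            mito_threshold < 1, top_n >= 1, min_set_size >= 1,
            n_gene_sets >= 1, length(gene_set_size_range) == 2,
            gene_set_size_range[1] >= 2,
            gene_set_size_range[2] >= gene_set_size_range[1])
  cfg <- list(sim = sim, alpha = alpha, fold = fold,
              mito_threshold = mito_threshold, top_n = top_n,
              min_set_size = min_set_size, min_expr = min_expr,
              profile_norm = match.arg(profile_norm, c("cp10k", "raw")),
              n_gene_sets = n_gene_sets,
              gene_set_size_range = gene_set_size_range,
              report_genes = report_genes, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Random gene-set collection with optional planted sets
#'
#' Draws `n_sets` random sets over the gene universe and appends any
#' `planted` sets verbatim; used to exercise the Stouffer stage on
#' synthetic data where planted sets carry genuine signal.
#'
#' @param genes gene universe.
#' @param n_sets number of random sets.
#' @param size_range inclusive range of random set sizes.
#' @param planted named list of gene-id vectors appended as-is.
#' @param seed integer seed.
#' @return a `gene_set_collection`.
#' @export
make_gene_sets <- function(genes, n_sets = 50, size_range = c(10, 50),
                           planted = list(), seed = 1L) {
  set.seed(seed)
  sets <- lapply(seq_len(n_sets), function(i) {
    sample(genes, sample(size_range[1]:size_range[2], 1))
  })
  names(sets) <- sprintf("random_set_%03d", seq_len(n_sets))
  sets <- c(sets, planted)
  desc <- stats::setNames(
    c(rep("random background set", n_sets),
      rep("planted set", length(planted))), names(sets))
  structure(list(sets = sets, descriptions = desc),
            class = "gene_set_collection")
}

#' Run the full synthetic pipeline
#'
#' Simulates the paired cohort, runs differential expression for every
#' (non-reference group vs reference) contrast in each compartment, scores
#' gene sets by the Stouffer method in both directionality modes, performs
#' the joint top-variable-gene PCA and the Venn partitions, filters and
#' aggregates the single-nucleus matrix, applies the twofold specificity
#' rule and superimposes the advanced-disease DEG sets onto cell types.
#' All outputs are written as TSV under `out_dir` along with a
#' `manifest.json` recording every parameter; a rerun with the same
#' configuration reproduces all outputs bit-identically.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created).
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## simulate
  bulk <- stage("simulate", simulate_bulk(config$sim))
  sn <- stage("simulate", simulate_sn(config$sim))
  data_dir <- file.path(out_dir, "data")
  dir.create(data_dir, showWarnings = FALSE)
  write_counts_tsv(bulk$counts_glomeruli, file.path(data_dir, "counts_glomeruli.tsv"))
  write_counts_tsv(bulk$counts_cortex, file.path(data_dir, "counts_cortex.tsv"))
  write_sample_table(bulk$sample_table, file.path(data_dir, "samples.tsv"))
  write_gene_annotation(bulk$gene_annotation, file.path(data_dir, "genes.tsv"))
  write_mtx(sn$counts, file.path(data_dir, "sn"),
            is_mito = sn$gene_annotation$is_mito)
  write_labels(sn$labels, file.path(data_dir, "sn", "labels.tsv"))
  write_truth(bulk$truth, file.path(data_dir, "truth_bulk"))
  write_truth(sn$truth, file.path(data_dir, "truth_sn"))

  ## differential expression per compartment x contrast
  groups <- config$sim$groups
  contrasts <- lapply(groups[-1], function(g) c(g, groups[1]))
  counts_by_comp <- list(glomeruli = bulk$counts_glomeruli,
                         cortex = bulk$counts_cortex)
  de <- list(); degs <- list()
  for (comp in names(counts_by_comp)) {
    for (ct in contrasts) {
      key <- paste0(comp, ".", gsub("[^A-Za-z0-9]+", "", ct[1]),
                    "_vs_", gsub("[^A-Za-z0-9]+", "", ct[2]))
      res <- stage("de", nb_wald_test(
        counts_by_comp[[comp]],
        bulk$sample_table[bulk$sample_table$compartment == comp, ],
        contrast = ct, alpha = config$alpha))
      de[[key]] <- res
      degs[[key]] <- call_degs(res, config$alpha)
      write_tsv_plain(res, file.path(out_dir, paste0("de_", key, ".tsv")))
    }
  }

  ## gene sets: random collection plus planted per-compartment DEG sets
  truth_deg <- bulk$truth$deg_table
  adv <- paste0(groups[length(groups)], "_vs_", groups[1])
  planted <- list()
  for (comp in names(counts_by_comp)) {
    ids <- unique(truth_deg$gene_id[truth_deg$compartment == comp &
                                      truth_deg$contrast == adv])
    if (length(ids) >= config$min_set_size) {
      planted[[paste0("planted_deg_", comp)]] <- ids
    }
  }
  collection <- make_gene_sets(rownames(bulk$counts_cortex),
                               n_sets = config$n_gene_sets,
                               size_range = config$gene_set_size_range,
                               planted = planted, seed = config$seed)
  write_gmt(collection, file.path(data_dir, "gene_sets.gmt"))
  gsa <- list()
  for (key in names(de)) {
    for (mode in c("nondirectional", "directional")) {
      gkey <- paste0(key, ".", mode)
      gsa[[gkey]] <- stage("gsa", gsa_run(de[[key]], collection, mode = mode,
                                          min_set_size = config$min_set_size))
      write_tsv_plain(gsa[[gkey]], file.path(out_dir, paste0("gsa_", gkey, ".tsv")))
    }
  }

  ## compartment comparison
  joint <- cbind(bulk$counts_glomeruli, bulk$counts_cortex)
  sf <- stage("compare", size_factors(joint, pseudo_reference = TRUE))
  normed <- sweep(joint, 2, sf, "/")
  hvg <- top_variable_genes(normed, n = min(config$top_n, nrow(normed)))
  pca <- stage("compare", pca_samples(normed, gene_subset = hvg))
  scores <- data.frame(sample_id = rownames(pca$scores),
                       pca$scores[, seq_len(min(5, ncol(pca$scores)))],
                       check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_plain(scores, file.path(out_dir, "pca_scores.tsv"))
  write_tsv_plain(data.frame(pc = seq_along(pca$var_explained),
                             var_explained_pct = pca$var_explained),
                  file.path(out_dir, "pca_variance.tsv"))

  venns <- list()
  for (ct in contrasts) {
    lab <- gsub("[^A-Za-z0-9]+", "", ct[1])
    key_g <- paste0("glomeruli.", lab, "_vs_", gsub("[^A-Za-z0-9]+", "", ct[2]))
    key_c <- paste0("cortex.", lab, "_vs_", gsub("[^A-Za-z0-9]+", "", ct[2]))
    venns[[lab]] <- venn_counts(degs[[key_g]], degs[[key_c]])
  }
  venn_df <- do.call(rbind, lapply(names(venns), function(nm) {
    data.frame(contrast = nm, t(venns[[nm]]$counts), stringsAsFactors = FALSE)
  }))
  write_tsv_plain(venn_df, file.path(out_dir, "venn.tsv"))

  ## RPKM group report for the top advanced-disease glomerular DEGs
  rpkm_mat <- rpkm(joint, stats::setNames(bulk$gene_annotation$length_bp,
                                          bulk$gene_annotation$gene_id))
  adv_label <- paste0(gsub("[^A-Za-z0-9]+", "", groups[length(groups)]),
                      "_vs_", gsub("[^A-Za-z0-9]+", "", groups[1]))
  res_adv <- de[[paste0("glomeruli.", adv_label)]]
  top_genes <- utils::head(res_adv$gene_id[order(res_adv$padj)],
                           config$report_genes)
  report <- gene_group_report(rpkm_mat, bulk$sample_table, top_genes)
  write_tsv_plain(report, file.path(out_dir, "gene_report.tsv"))

  ## single-nucleus integration (advanced-disease contrast)
  filt <- stage("integrate", filter_nuclei_mito(
    sn$counts, sn$gene_annotation$is_mito, threshold = config$mito_threshold))
  labels_kept <- sn$labels[sn$labels$barcode %in% colnames(filt), ]
  profiles <- stage("integrate", celltype_profiles(filt, labels_kept,
                                                   norm = config$profile_norm))
  spec <- assign_specific_genes(profiles, fold = config$fold,
                                min_expr = config$min_expr)
  key_g <- paste0("glomeruli.", adv_label)
  key_c <- paste0("cortex.", adv_label)
  summary <- superimpose_degs(spec, degs[[key_g]], degs[[key_c]])
  write_tsv_plain(spec, file.path(out_dir, "specificity_map.tsv"))
  write_tsv_plain(summary, file.path(out_dir, "integration_summary.tsv"))
  cellcounts <- cell_counts_per_type(labels_kept)
  write_tsv_plain(data.frame(cell_type = rownames(cellcounts), cellcounts,
                             check.names = FALSE, stringsAsFactors = FALSE),
                  file.path(out_dir, "cell_counts.tsv"))

  manifest <- list(
    package = "glomint",
    version = as.character(utils::packageVersion("glomint")),
    seed = config$seed,
    parameters = list(
      alpha = config$alpha, fold = config$fold,
      mito_threshold = config$mito_threshold, top_n = config$top_n,
      min_set_size = config$min_set_size, min_expr = config$min_expr,
      profile_norm = config$profile_norm,
      n_gene_sets = config$n_gene_sets,
      gene_set_size_range = config$gene_set_size_range,
      report_genes = config$report_genes
    ),
    sim = config$sim[setdiff(names(config$sim), "compartment_mix")],
    compartment_mix = apply(config$sim$compartment_mix, 1, as.list)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(bulk = bulk, sn = sn, de = de, degs = degs, gsa = gsa,
                 pca = pca, venns = venns, report = report,
                 profiles = profiles, specificity = spec,
                 integration = summary, cell_counts = cellcounts))
}
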