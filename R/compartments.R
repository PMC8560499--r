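#' Select the most variable genes
#'
#' Ranks genes by the variance of `log2(x + 1)` across all samples and
#' returns the top `n`; exact-variance ties are broken by gene-id
#' lexicographic order.
#'
#' @param mat numeric genes x samples matrix (normalized counts or RPKM).
#' @param n number of genes to return (default 500).
#' @return character vector of gene ids, ranked.
#' @export
top_variable_genes <- function(mat, n = 500) {
  mat <- as.matrix(mat)
  if (n <= 0) stop("n must be positive")
  if (n > nrow(mat)) stop("n exceeds the number of genes")
  v <- apply(log2(mat + 1), 1, stats::var)
  ord <- order(-v, rownames(mat))
  rownames(mat)[ord][seq_len(n)]
}

#' Principal component analysis of samples
#'
#' Eigen-decomposition of the sample covariance of gene-centered
#' `log2(x + 1)` expression over a gene subset. Variance explained per
#' component is its eigenvalue as a percentage of the total; each component
#' is oriented so that its largest-magnitude gene loading is positive.
#'
#' @param mat numeric genes x samples matrix.
#' @param gene_subset gene ids to use (e.g. from [top_variable_genes()]);
#'   `NULL` uses all genes.
#' @param log_transform apply `log2(x + 1)` (set `FALSE` if `mat` is
#'   already on log scale).
#' @return list of class `pca_result`: `scores` (samples x PCs),
#'   `var_explained` (percent per PC), `loadings` (genes x PCs), `genes`.
#' @export
pca_samples <- function(mat, gene_subset = NULL, log_transform = TRUE) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("PCA needs at least 2 samples")
  if (!is.null(gene_subset)) {
    missing <- setdiff(gene_subset, rownames(mat))
    if (length(missing)) stop("gene_subset contains unknown ids")
    mat <- mat[gene_subset, , drop = FALSE]
  }
  x <- if (log_transform) log2(mat + 1) else mat
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  var_explained <- 100 * ev / sum(ev)
  # orient: largest-|loading| positive per PC
  for (k in seq_len(ncol(pc$rotation))) {
    j <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[j, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  structure(list(scores = pc$x, var_explained = var_explained,
                 loadings = pc$rotation, genes = rownames(mat)),
            class = "pca_result")
}

#' Two-set Venn partition of DEG lists
#'
#' @param degs_a,degs_b character vectors of gene ids (duplicates ignored).
#' @return list of class `venn_partition`: `only_a`, `only_b`, `shared`
#'   (id vectors) and `counts` (named integer vector).
#' @export
venn_counts <- function(degs_a, degs_b) {
  a <- unique(degs_a); b <- unique(degs_b)
  shared <- intersect(a, b)
  only_a <- setdiff(a, b)
  only_b <- setdiff(b, a)
  structure(list(
    only_a = only_a, only_b = only_b, shared = shared,
    counts = c(only_a = length(only_a), shared = length(shared),
               only_b = length(only_b))
  ), class = "venn_partition")
}

#' Group-level RPKM report for selected genes
#'
#' Mean and standard error of the mean (sd over `sqrt(n)`, sample sd with
#' `n - 1` denominator) of RPKM per (gene, group, compartment) cell.
#' Singleton cells report an s.e.m. of 0 with a warning.
#'
#' @param rpkm_mat genes x samples RPKM matrix.
#' @param sample_table data.frame with `sample_id`, `group`, `compartment`.
#' @param genes gene ids to report.
#' @return data.frame: `gene_id`, `group`, `compartment`, `n`, `mean_rpkm`,
#'   `sem_rpkm`.
#' @export
gene_group_report <- function(rpkm_mat, sample_table, genes) {
  missing <- setdiff(genes, rownames(rpkm_mat))
  if (length(missing)) {
    stop("unknown gene id(s): ", paste(utils::head(missing, 5), collapse = ", "))
  }
  st <- sample_table[sample_table$sample_id %in% colnames(rpkm_mat), ]
  cells <- unique(st[, c("group", "compartment")])
  rows <- list()
  singleton <- FALSE
  for (g in genes) {
    for (i in seq_len(nrow(cells))) {
      ids <- st$sample_id[st$group == cells$group[i] &
                            st$compartment == cells$compartment[i]]
      x <- rpkm_mat[g, ids]
      n <- length(x)
      sem <- if (n > 1) stats::sd(x) / sqrt(n) else { singleton <- TRUE; 0 }
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, group = cells$group[i],
        compartment = cells$compartment[i], n = n,
        mean_rpkm = mean(x), sem_rpkm = sem, stringsAsFactors = FALSE
      )
    }
  }
  if (singleton) warning("groups with a single sample report s.e.m. = 0")
  do.call(rbind, rows)
}
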