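#' Remove nuclei with high mitochondrial content
#'
#' Nuclear RNA should be essentially free of mitochondrial transcripts, so
#' nuclei whose mitochondrial read fraction exceeds the threshold (default
#' 0.25%, strict `>`; a nucleus at exactly the threshold is retained) are
#' removed. Nuclei with zero total counts are also removed with a message.
#'
#' @param counts genes x nuclei count matrix (dense or `dgCMatrix`).
#' @param is_mito logical per-gene mitochondrial flag (named by gene id or
#'   in row order). When no gene is flagged, a warning is issued and the
#'   filter is a no-op.
#' @param threshold mitochondrial fraction above which a nucleus is removed.
#' @return the filtered matrix, with attributes `removed_barcodes` and
#'   `mito_fraction` (per retained nucleus).
#' @export
filter_nuclei_mito <- function(counts, is_mito, threshold = 0.0025) {
  if (!is.null(names(is_mito)) && !is.null(rownames(counts))) {
    is_mito <- is_mito[rownames(counts)]
  }
  stopifnot(length(is_mito) == nrow(counts))
  if (!any(is_mito, na.rm = TRUE)) {
    warning("no mitochondrial genes flagged; mitochondrial filter is a no-op")
    return(counts)
  }
  total <- Matrix::colSums(counts)
  mito <- Matrix::colSums(counts[which(is_mito), , drop = FALSE])
  zero <- total == 0
  if (any(zero)) {
    message("filter_nuclei_mito: removing ", sum(zero),
            " nucleus(ei) with zero total counts")
  }
  frac <- ifelse(zero, NA_real_, mito / total)
  keep <- !zero & frac <= threshold
  out <- counts[, keep, drop = FALSE]
  attr(out, "removed_barcodes") <- colnames(counts)[!keep]
  attr(out, "mito_fraction") <- frac[keep]
  out
}

#' Per-cell-type mean expression profiles
#'
#' Aggregates nucleus counts into a cell-type x gene matrix of mean
#' expression. By default each nucleus is scaled to counts-per-10k before
#' averaging; `norm = "raw"` averages raw counts.
#'
#' @param counts genes x nuclei count matrix.
#' @param labels data.frame with columns `barcode` and `cell_type`; every
#'   barcode must exist in the matrix. Only labelled nuclei contribute.
#' @param norm `"cp10k"` or `"raw"`.
#' @return cell-type x gene numeric matrix with attribute `n_nuclei`
#'   (named integer vector of nuclei per type).
#' @export
celltype_profiles <- function(counts, labels, norm = c("cp10k", "raw")) {
  norm <- match.arg(norm)
  stopifnot(all(c("barcode", "cell_type") %in% names(labels)))
  missing <- setdiff(labels$barcode, colnames(counts))
  if (length(missing)) {
    stop("labels reference barcodes absent from the matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  m <- counts[, labels$barcode, drop = FALSE]
  if (norm == "cp10k") {
    tot <- Matrix::colSums(m)
    if (any(tot == 0)) {
      keep <- tot > 0
      warning("dropping ", sum(!keep), " zero-count nucleus(ei) from profiles")
      m <- m[, keep, drop = FALSE]
      labels <- labels[keep, , drop = FALSE]
      tot <- tot[keep]
    }
    m <- m %*% Matrix::Diagonal(x = 1e4 / tot)
  }
  types <- sort(unique(labels$cell_type))
  ind <- Matrix::sparseMatrix(
    i = seq_len(nrow(labels)), j = match(labels$cell_type, types),
    x = 1, dims = c(nrow(labels), length(types))
  )
  n_per <- Matrix::colSums(ind)
  prof <- t(as.matrix(m %*% ind %*% Matrix::Diagonal(x = 1 / n_per)))
  dimnames(prof) <- list(types, rownames(counts))
  attr(prof, "n_nuclei") <- stats::setNames(as.integer(n_per), types)
  prof
}

#' Assign cell-type-specific genes by the twofold rule
#'
#' A gene is specific to a cell type when (1) that cell type has the
#' highest expression of the gene and (2) the expression is at least
#' `fold`-fold (default twofold, inclusive) above the cell type with the
#' second-highest expression. Exact ties at the top violate criterion (1)
#' and leave the gene unassigned. A gene whose runner-up expression is zero
#' is assigned when the top expression is positive (the ratio is recorded
#' as infinite). A minimum-expression floor on the top value suppresses
#' noise-driven specificity in sparse data.
#'
#' @param profiles cell-type x gene matrix from [celltype_profiles()].
#' @param fold specificity fold threshold (inclusive; default 2).
#' @param min_expr minimum top expression for assignment, in the units of
#'   `profiles` (default 0.1 counts-per-10k).
#' @return data.frame of class `specificity_map`: `gene_id`, `cell_type`
#'   (NA when unassigned), `top_cell_type`, `runner_up_cell_type`,
#'   `top_expr`, `runner_up_expr`, `fold_ratio` (Inf when the runner-up
#'   is zero).
#' @export
assign_specific_genes <- function(profiles, fold = 2, min_expr = 0.1) {
  if (nrow(profiles) < 2) stop("specificity needs >= 2 cell types")
  types <- rownames(profiles)
  top_i <- apply(profiles, 2, which.max)
  top <- profiles[cbind(top_i, seq_len(ncol(profiles)))]
  second <- apply(profiles, 2, function(v) {
    s <- sort(v, decreasing = TRUE)
    s[2]
  })
  runner_i <- vapply(seq_len(ncol(profiles)), function(j) {
    v <- profiles[, j]
    v[top_i[j]] <- -Inf
    which.max(v)
  }, 0L)
  tie <- vapply(seq_len(ncol(profiles)), function(j) {
    sum(profiles[, j] == top[j]) > 1
  }, logical(1))
  ratio <- ifelse(second == 0, Inf, top / second)
  assigned <- !tie & top > 0 & top >= min_expr & ratio >= fold
  out <- data.frame(
    gene_id = colnames(profiles),
    cell_type = ifelse(assigned, types[top_i], NA_character_),
    top_cell_type = types[top_i],
    runner_up_cell_type = types[runner_i],
    top_expr = top, runner_up_expr = second, fold_ratio = ratio,
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("specificity_map", "data.frame")
  out
}

#' Superimpose compartment DEG sets onto cell types
#'
#' Categorizes every cell-type-specific gene by whether it is
#' differentially expressed in the glomeruli, the cortex, both
#' compartments, or neither, and tabulates counts per cell type.
#'
#' @param spec a `specificity_map` from [assign_specific_genes()].
#' @param degs_glom,degs_cortex character vectors of DEG gene ids.
#' @return data.frame of class `integration_summary`: `cell_type`,
#'   `n_specific`, `glomeruli`, `cortex`, `both`, `none` (one row per cell
#'   type with at least one specific gene); attribute `gene_categories`
#'   carries the per-gene assignment.
#' @export
superimpose_degs <- function(spec, degs_glom, degs_cortex) {
  assigned <- spec[!is.na(spec$cell_type), , drop = FALSE]
  in_g <- assigned$gene_id %in% degs_glom
  in_c <- assigned$gene_id %in% degs_cortex
  category <- ifelse(in_g & in_c, "both",
              ifelse(in_g, "glomeruli",
              ifelse(in_c, "cortex", "none")))
  per_gene <- data.frame(gene_id = assigned$gene_id,
                         cell_type = assigned$cell_type,
                         category = category, stringsAsFactors = FALSE)
  types <- sort(unique(assigned$cell_type))
  tab <- table(factor(per_gene$cell_type, levels = types),
               factor(per_gene$category,
                      levels = c("glomeruli", "cortex", "both", "none")))
  out <- data.frame(
    cell_type = types,
    n_specific = as.integer(rowSums(tab)),
    glomeruli = as.integer(tab[, "glomeruli"]),
    cortex = as.integer(tab[, "cortex"]),
    both = as.integer(tab[, "both"]),
    none = as.integer(tab[, "none"]),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "gene_categories") <- per_gene
  class(out) <- c("integration_summary", "data.frame")
  out
}

#' Nucleus counts per cell type and animal
#'
#' Contingency table of labelled nuclei by cell population and animal.
#'
#' @param labels data.frame with `cell_type` and `animal_id` columns.
#' @return integer matrix, cell types x animals; the sum equals the number
#'   of labelled nuclei.
#' @export
cell_counts_per_type <- function(labels) {
  stopifnot(nrow(labels) > 0,
            all(c("cell_type", "animal_id") %in% names(labels)))
  as.matrix(unclass(table(labels$cell_type, labels$animal_id)))
}
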