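# Plain TSV helpers shared by the readers/writers. All tables are
# tab-separated with a header row; gene ids are opaque strings.

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_plain <- function(path, col_classes) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE,
                          colClasses = unname(col_classes))
  missing <- setdiff(names(col_classes), names(df))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  }
  df[, names(col_classes), drop = FALSE]
}

#' Write a count matrix to TSV
#'
#' Genes as rows; the first column (`gene_id`) holds gene identifiers,
#' remaining columns are samples.
#'
#' @param counts genes x samples integer matrix with dimnames.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_plain(df, path)
}

#' Read a count matrix from TSV
#'
#' Expects the layout of [write_counts_tsv()]: column 1 gene ids, one
#' column per sample, integer non-negative counts. Duplicate gene or
#' sample ids, non-integer or negative counts, ragged rows and an empty
#' data section are each rejected with a distinct message.
#'
#' @param path TSV path.
#' @return integer matrix, genes x samples.
#' @export
read_counts_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("malformed TSV (", conditionMessage(e), ")")
  )
  if (nrow(df) == 0) stop("count matrix has an empty data section: ", path)
  if (ncol(df) < 2) stop("count matrix needs a gene_id column plus >= 1 sample")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicated gene id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (anyDuplicated(names(df)[-1])) {
    stop("duplicated sample id(s): ",
         paste(unique(names(df)[-1][duplicated(names(df)[-1])]), collapse = ", "))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric counts in ", path)
  if (any(!is.finite(m)) || any(m < 0) || any(m != round(m))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' Write / read the sample table
#'
#' Columns: `sample_id`, `group`, `compartment`, `animal_id`.
#'
#' @param sample_table the table to write.
#' @param path TSV path.
#' @return `write_sample_table`: invisibly `path`; `read_sample_table`:
#'   the data.frame.
#' @export
write_sample_table <- function(sample_table, path) {
  write_tsv_plain(sample_table, path)
}

#' @rdname write_sample_table
#' @export
read_sample_table <- function(path) {
  st <- read_tsv_plain(path, c(sample_id = "character", group = "character",
                               compartment = "character",
                               animal_id = "character"))
  if (anyDuplicated(st$sample_id)) stop("duplicated sample ids in ", path)
  st
}

#' Write / read gene annotation
#'
#' Columns: `gene_id`, `length_bp`, `is_mito`.
#' @param annotation the annotation data.frame.
#' @param path TSV path.
#' @return the annotation data.frame (reader) or `path` (writer).
#' @export
write_gene_annotation <- function(annotation, path) {
  write_tsv_plain(annotation, path)
}

#' @rdname write_gene_annotation
#' @export
read_gene_annotation <- function(path) {
  read_tsv_plain(path, c(gene_id = "character", length_bp = "integer",
                         is_mito = "logical"))
}

#' Write a sparse nucleus matrix as MatrixMarket MTX plus sidecars
#'
#' Writes `matrix.mtx` (coordinate format, 1-based), `features.tsv`
#' (`gene_id`, `is_mito`) and `barcodes.tsv` under `dir`.
#'
#' @param counts genes x nuclei `dgCMatrix` (or coercible) with dimnames.
#' @param dir output directory.
#' @param is_mito per-gene logical flag; `NULL` derives it from an `mt-`
#'   gene-id prefix.
#' @return invisibly, the three paths.
#' @export
write_mtx <- function(counts, dir, is_mito = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dn <- dimnames(counts)
  counts <- methods::as(methods::as(methods::as(
    counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  dimnames(counts) <- dn
  if (is.null(is_mito)) is_mito <- startsWith(rownames(counts), "mt-")
  paths <- c(matrix = file.path(dir, "matrix.mtx"),
             features = file.path(dir, "features.tsv"),
             barcodes = file.path(dir, "barcodes.tsv"))
  Matrix::writeMM(counts, paths["matrix"])
  write_tsv_plain(data.frame(gene_id = rownames(counts), is_mito = is_mito,
                             stringsAsFactors = FALSE), paths["features"])
  writeLines(colnames(counts), paths["barcodes"])
  invisible(paths)
}

#' Read a MatrixMarket nucleus matrix with features and barcodes
#'
#' Dimensions must match the sidecar files. The mitochondrial flag comes
#' from the `is_mito` column of the features file when present, otherwise
#' from an `mt-` gene-id prefix.
#'
#' @param matrix_path MTX file (coordinate, 1-based indices).
#' @param features_path TSV with `gene_id` (and optionally `is_mito`).
#' @param barcodes_path one barcode per line.
#' @return genes x nuclei `dgCMatrix` with attribute `is_mito`.
#' @export
read_mtx <- function(matrix_path, features_path, barcodes_path) {
  m <- Matrix::readMM(matrix_path)
  feats <- utils::read.delim(features_path, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(feats)) stop("features file lacks gene_id column")
  barcodes <- readLines(barcodes_path)
  if (nrow(feats) != nrow(m)) {
    stop("dimension mismatch: MTX declares ", nrow(m), " genes but features ",
         "file has ", nrow(feats), " rows")
  }
  if (length(barcodes) != ncol(m)) {
    stop("dimension mismatch: MTX declares ", ncol(m), " nuclei but barcodes ",
         "file has ", length(barcodes), " rows")
  }
  if (anyDuplicated(barcodes)) stop("duplicated barcodes")
  m <- methods::as(methods::as(methods::as(
    m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  dimnames(m) <- list(feats$gene_id, barcodes)
  attr(m, "is_mito") <- if ("is_mito" %in% names(feats)) {
    as.logical(feats$is_mito)
  } else startsWith(feats$gene_id, "mt-")
  m
}

#' Write / read nucleus labels
#'
#' Columns: `barcode`, `cell_type`, `animal_id`.
#' @param labels the labels data.frame.
#' @param path TSV path.
#' @return the labels data.frame (reader) or `path` (writer).
#' @export
write_labels <- function(labels, path) write_tsv_plain(labels, path)

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  read_tsv_plain(path, c(barcode = "character", cell_type = "character",
                         animal_id = "character"))
}
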