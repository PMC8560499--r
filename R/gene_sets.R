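#' Read a GMT gene-set collection
#'
#' GMT is tab-separated: set name, description, then member gene ids.
#' Duplicate members within a line are collapsed.
#'
#' @param path path to a GMT file.
#' @return object of class `gene_set_collection`: a list with `sets`
#'   (named list of character vectors) and `descriptions` (named character).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) {
    stop("GMT lines with fewer than 3 fields: line(s) ",
         paste(which(bad), collapse = ", "))
  }
  nm <- vapply(parts, `[[`, "", 1)
  if (anyDuplicated(nm)) stop("duplicate set names in GMT: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  desc <- stats::setNames(vapply(parts, `[[`, "", 2), nm)
  structure(list(sets = sets, descriptions = desc),
            class = "gene_set_collection")
}

#' Write a gene-set collection to GMT
#' @param collection `gene_set_collection` or named list of gene-id vectors.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  if (inherits(collection, "gene_set_collection")) {
    sets <- collection$sets
    desc <- collection$descriptions
  } else {
    sets <- collection
    desc <- stats::setNames(rep("na", length(sets)), names(sets))
  }
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Per-gene z-scores from differential-expression p-values
#'
#' Converts gene-level p-values to standard-normal scores for Stouffer
#' combination. In `"nondirectional"` mode `z = qnorm(1 - p/2)` (magnitude
#' only); in `"directional"` mode the score is signed by the log2
#' fold-change. P-values are floored at 1e-300.
#'
#' @param de a `de_result` (needs `gene_id`, `pvalue`, `log2fc`).
#' @param mode `"nondirectional"` or `"directional"`.
#' @return named numeric vector of z-scores over genes with a p-value.
#' @export
gene_level_z <- function(de, mode = c("nondirectional", "directional")) {
  mode <- match.arg(mode)
  stopifnot(all(c("gene_id", "pvalue", "log2fc") %in% names(de)))
  ok <- !is.na(de$pvalue)
  p <- pmax(de$pvalue[ok], 1e-300)
  # upper-tail form of qnorm(1 - p/2): stays finite for tiny p
  z <- stats::qnorm(p / 2, lower.tail = FALSE)
  if (mode == "directional") z <- sign(de$log2fc[ok]) * z
  stats::setNames(z, de$gene_id[ok])
}

#' Stouffer statistic for one gene set
#'
#' `Z = sum(z_g) / sqrt(n)` over the set members present in the z universe.
#' The p-value is upper-tail for non-directional scores and two-sided for
#' directional scores.
#'
#' @param z named per-gene z vector (the universe).
#' @param set character vector of member gene ids (duplicates collapsed).
#' @param mode directionality convention used to build `z`.
#' @return list with `Z`, `pvalue`, `n`.
#' @export
stouffer_set_stat <- function(z, set,
                              mode = c("nondirectional", "directional")) {
  mode <- match.arg(mode)
  members <- intersect(unique(set), names(z))
  n <- length(members)
  if (n == 0) stop("gene set has empty intersection with the universe")
  Z <- sum(z[members]) / sqrt(n)
  p <- if (mode == "directional") 2 * stats::pnorm(-abs(Z)) else {
    stats::pnorm(Z, lower.tail = FALSE)
  }
  list(Z = Z, pvalue = p, n = n)
}

#' Gene-set perturbation analysis by the Stouffer method
#'
#' Scores every set of a collection against the gene-level z-scores derived
#' from a differential-expression result, adjusts across sets by
#' Benjamini-Hochberg, and reports the degree of perturbation as
#' `-log10(adjusted p)`. Sets smaller than `min_set_size` after
#' intersection with the tested universe are dropped with a message.
#'
#' @param de a `de_result`.
#' @param collection `gene_set_collection` or named list of gene-id vectors.
#' @param mode `"nondirectional"` (perturbation regardless of direction) or
#'   `"directional"` (coherent up/down regulation).
#' @param min_set_size minimum members in the universe (default 5).
#' @return data.frame: `set`, `n`, `Z`, `pvalue`, `padj`,
#'   `neglog10_padj`, `mode`, `direction`, sorted by `padj`.
#' @export
gsa_run <- function(de, collection,
                    mode = c("nondirectional", "directional"),
                    min_set_size = 5) {
  mode <- match.arg(mode)
  sets <- if (inherits(collection, "gene_set_collection")) collection$sets
          else collection
  if (!length(sets)) stop("empty gene-set collection")
  z <- gene_level_z(de, mode)
  sizes <- vapply(sets, function(s) length(intersect(unique(s), names(z))), 0L)
  if (all(sizes == 0)) stop("no overlap between gene sets and the DE universe")
  dropped <- sum(sizes > 0 & sizes < min_set_size)
  missing_members <- sum(vapply(sets, function(s)
    sum(!unique(s) %in% names(z)), 0L))
  if (dropped > 0 || missing_members > 0) {
    message("gsa_run: dropped ", dropped, " set(s) below min_set_size; ",
            missing_members, " member gene(s) absent from the DE universe")
  }
  keep <- names(sets)[sizes >= min_set_size]
  if (!length(keep)) stop("no gene set reaches min_set_size in the universe")
  stats_list <- lapply(sets[keep], function(s) stouffer_set_stat(z, s, mode))
  res <- data.frame(
    set = keep,
    n = vapply(stats_list, `[[`, 0L, "n"),
    Z = vapply(stats_list, `[[`, 0, "Z"),
    pvalue = vapply(stats_list, `[[`, 0, "pvalue"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  res$padj <- bh_adjust(res$pvalue)
  res$neglog10_padj <- -log10(pmax(res$padj, 1e-300))
  res$mode <- mode
  res$direction <- if (mode == "directional") {
    ifelse(res$Z >= 0, "distinct-directional up", "distinct-directional down")
  } else "non-directional"
  res[order(res$padj, res$pvalue, res$set), , drop = FALSE]
}
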