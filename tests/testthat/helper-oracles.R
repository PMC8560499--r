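# Independent brute-force oracles, coded directly from the defining
# formulas and kept free of any package internals.

# BH step-up: q_(i) = min_{j >= i} p_(j) * n / j, capped at 1.
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# median-of-ratios size factors, straight from the definition
size_factors_brute <- function(counts) {
  ref <- apply(counts, 1, function(x) exp(mean(log(x))))
  keep <- apply(counts, 1, function(x) all(x > 0))
  f <- apply(counts[keep, , drop = FALSE], 2, function(col) {
    stats::median(col / ref[keep])
  })
  f / exp(mean(log(f)))
}

rpkm_brute <- function(counts, lengths) {
  out <- counts * 0
  for (j in seq_len(ncol(counts))) {
    for (g in seq_len(nrow(counts))) {
      out[g, j] <- counts[g, j] * 1e9 / (lengths[g] * sum(counts[, j]))
    }
  }
  out
}

stouffer_brute <- function(z, genes) {
  members <- unique(genes)
  members <- members[members %in% names(z)]
  sum(z[members]) / sqrt(length(members))
}

# group means of per-nucleus normalized expression, loop form
profiles_brute <- function(counts, labels, cp10k = TRUE) {
  m <- as.matrix(counts)[, labels$barcode, drop = FALSE]
  if (cp10k) m <- sweep(m, 2, colSums(m), "/") * 1e4
  types <- sort(unique(labels$cell_type))
  out <- matrix(0, length(types), nrow(m),
                dimnames = list(types, rownames(m)))
  for (ty in types) {
    out[ty, ] <- rowMeans(m[, labels$cell_type == ty, drop = FALSE])
  }
  out
}

# small deterministic count matrix for I/O and normalization tests
tiny_counts <- function(n_genes = 20, n_samples = 4, seed = 42,
                        lambda = 30) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_samples, lambda), n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  storage.mode(m) <- "integer"
  m
}

# a minimal de_result-shaped data.frame from explicit p-values / signs
fake_de <- function(pvalue, log2fc = rep(1, length(pvalue)),
                    gene_id = sprintf("g%04d", seq_along(pvalue))) {
  data.frame(gene_id = gene_id, base_mean = 10, log2fc = log2fc,
             lfc_se = 1, stat = 0, pvalue = pvalue,
             padj = pmin(1, pvalue), is_deg = FALSE, tested = TRUE,
             stringsAsFactors = FALSE)
}
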