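#' Simulation configuration for the synthetic kidney cohort
#'
#' Builds and validates the configuration driving [simulate_bulk()] and
#' [simulate_sn()]. Defaults emulate the study design the pipeline was built
#' for: three phenotype groups (db/m controls, uninephrectomized db/db "UNx",
#' and UNx with renin-driven hypertension "UNx-Renin") profiled in two kidney
#' compartments (laser-captured glomeruli and whole cortex), plus a
#' single-nucleus matrix over ~21 kidney cell populations sharing the same
#' gene universe.
#'
#' Counts are negative binomial with variance `mu + dispersion * mu^2`.
#' Expected bulk means are a cell-type signature mixture: each compartment has
#' its own mixing weights over cell-type signatures, with the glomerular
#' compartment concentrated on podocyte-, mesangial- and glomerular
#' endothelial-like signatures. Because marker genes differ between cell
#' types by `marker_fold`, the two compartments differ far more than the
#' phenotype groups do, so compartment identity dominates total variance —
#' the structure the joint PCA is expected to recover.
#'
#' @param n_genes number of genes in the shared universe.
#' @param n_celltypes number of cell populations (default 21).
#' @param groups ordered group labels; the first is the reference.
#' @param n_per_group bulk samples per group per compartment (design range
#'   5–13).
#' @param n_nuclei_per_type nuclei simulated per cell type.
#' @param baseline_logmean_mu,baseline_logmean_sd log-normal parameters for
#'   per-gene baseline means (count scale).
#' @param dispersion per-gene NB dispersion for bulk counts.
#' @param deg_fraction fraction of genes planted as DEGs per
#'   (non-reference group, compartment) contrast.
#' @param deg_fold_range interval of planted fold-changes; lower bound > 1.
#'   Direction (up/down) is drawn 50/50 per planted gene.
#' @param marker_fraction fraction of genes planted as cell-type markers
#'   (split round-robin over cell types).
#' @param marker_fold planted marker fold over all other cell types.
#' @param marker_min_baseline detectability floor: cell-type markers and
#'   decoys are planted only on genes whose baseline mean exceeds this
#'   value, mirroring that curated marker genes are measurably expressed;
#'   `NULL` uses `exp(baseline_logmean_mu - baseline_logmean_sd)` (the
#'   ~16th baseline percentile).
#' @param lineage_marker_fraction fraction of genes planted as lineage
#'   programs — expressed `lineage_marker_fold`-fold higher in every cell
#'   type of one lineage (glomerular: the first three cell types; tubular:
#'   the rest). These emulate pan-lineage expression programs (e.g.
#'   slit-diaphragm versus solute-transport genes) and are what makes the
#'   compartments separate strongly; being tied within their lineage, they
#'   are never cell-type-specific under the twofold rule.
#' @param lineage_marker_fold fold applied to lineage program genes.
#' @param decoy_fraction,decoy_fold optional genes planted at a sub-threshold
#'   fold (for specificity-rule falsification experiments); recorded in the
#'   marker table with their fold.
#' @param compartment_mix 2 x n_celltypes matrix of mixing weights with
#'   rownames `c("glomeruli", "cortex")`, rows summing to 1; `NULL` builds
#'   the default glomerulus-enriched design.
#' @param lib_size_sd log-normal sd of per-sample bulk library-size factors.
#' @param nucleus_lib_size expected total counts per nucleus.
#' @param sn_lib_size_sd log-normal sd of per-nucleus library factors.
#' @param sn_dispersion NB dispersion for nucleus counts; 0 means Poisson.
#' @param mito_gene_fraction fraction of genes flagged mitochondrial (named
#'   with an `mt-` prefix).
#' @param mito_high_fraction fraction of nuclei planted with high
#'   mitochondrial content.
#' @param mito_high_level true mitochondrial fraction planted in those
#'   nuclei; must exceed the 0.25% QC threshold.
#' @param strict_deg_rounding if `TRUE`, error when `deg_fraction > 0` rounds
#'   to zero planted genes; otherwise plant at least one.
#' @param seed integer seed; identical configuration implies bit-identical
#'   output.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 4000,
                       n_celltypes = 21,
                       groups = c("db/m", "UNx", "UNx-Renin"),
                       n_per_group = 6,
                       n_nuclei_per_type = 100,
                       baseline_logmean_mu = log(50),
                       baseline_logmean_sd = 1,
                       dispersion = 0.1,
                       deg_fraction = 0.1,
                       deg_fold_range = c(2, 4),
                       marker_fraction = 0.3,
                       marker_fold = 4,
                       marker_min_baseline = NULL,
                       lineage_marker_fraction = 0.2,
                       lineage_marker_fold = 8,
                       decoy_fraction = 0,
                       decoy_fold = 1.5,
                       compartment_mix = NULL,
                       lib_size_sd = 0.2,
                       nucleus_lib_size = 5000,
                       sn_lib_size_sd = 0.3,
                       sn_dispersion = 0,
                       mito_gene_fraction = 0.005,
                       mito_high_fraction = 0.05,
                       mito_high_level = 0.02,
                       strict_deg_rounding = FALSE,
                       seed = 1L) {
  stopifnot(
    n_genes >= 1, n_celltypes >= 1, n_per_group >= 2,
    n_nuclei_per_type >= 1, length(groups) >= 2, !anyDuplicated(groups),
    dispersion >= 0, sn_dispersion >= 0,
    baseline_logmean_sd >= 0, lib_size_sd >= 0, sn_lib_size_sd >= 0,
    nucleus_lib_size > 0, mito_high_level > 0
  )
  stopifnot(marker_fold >= 1, lineage_marker_fold >= 1, decoy_fold >= 1)
  for (f in c(deg_fraction, marker_fraction, lineage_marker_fraction,
              decoy_fraction, mito_gene_fraction, mito_high_fraction)) {
    if (f < 0 || f > 1) stop("all fractions must lie in [0, 1]")
  }
  if (length(deg_fold_range) != 2 || deg_fold_range[1] <= 1 ||
      deg_fold_range[2] < deg_fold_range[1]) {
    stop("deg_fold_range must be an interval with lower bound > 1")
  }
  if (is.null(compartment_mix)) {
    compartment_mix <- default_compartment_mix(n_celltypes)
  }
  compartment_mix <- as.matrix(compartment_mix)
  if (nrow(compartment_mix) != 2 || ncol(compartment_mix) != n_celltypes) {
    stop("compartment_mix must be 2 x n_celltypes")
  }
  if (is.null(rownames(compartment_mix))) {
    rownames(compartment_mix) <- c("glomeruli", "cortex")
  }
  if (any(compartment_mix < 0) ||
      any(abs(rowSums(compartment_mix) - 1) > 1e-8)) {
    stop("compartment mixing weights must be non-negative and sum to 1")
  }
  cfg <- list(
    n_genes = as.integer(n_genes), n_celltypes = as.integer(n_celltypes),
    groups = groups, n_per_group = as.integer(n_per_group),
    n_nuclei_per_type = as.integer(n_nuclei_per_type),
    baseline_logmean_mu = baseline_logmean_mu,
    baseline_logmean_sd = baseline_logmean_sd,
    dispersion = dispersion, deg_fraction = deg_fraction,
    deg_fold_range = deg_fold_range, marker_fraction = marker_fraction,
    marker_fold = marker_fold,
    marker_min_baseline = if (is.null(marker_min_baseline)) {
      exp(baseline_logmean_mu - baseline_logmean_sd)
    } else marker_min_baseline,
    lineage_marker_fraction = lineage_marker_fraction,
    lineage_marker_fold = lineage_marker_fold,
    decoy_fraction = decoy_fraction,
    decoy_fold = decoy_fold, compartment_mix = compartment_mix,
    lib_size_sd = lib_size_sd, nucleus_lib_size = nucleus_lib_size,
    sn_lib_size_sd = sn_lib_size_sd, sn_dispersion = sn_dispersion,
    mito_gene_fraction = mito_gene_fraction,
    mito_high_fraction = mito_high_fraction,
    mito_high_level = mito_high_level,
    strict_deg_rounding = isTRUE(strict_deg_rounding),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Default compartment mixing weights
#'
#' Glomeruli are dominated by podocyte-, mesangial- and glomerular
#' endothelial-like signatures (cell types 1–3); cortex is mostly tubular
#' (the remaining types) with a small glomerular admixture, reflecting that
#' glomeruli are a minor fraction of cortical tissue.
#'
#' @param n_celltypes number of cell types (>= 1).
#' @return 2 x n_celltypes weight matrix with rows summing to 1.
#' @export
default_compartment_mix <- function(n_celltypes) {
  glom <- numeric(n_celltypes)
  cortex <- numeric(n_celltypes)
  k <- min(3L, n_celltypes)
  glom[seq_len(k)] <- c(0.45, 0.3, 0.25)[seq_len(k)]
  if (n_celltypes > k) {
    glom[(k + 1):n_celltypes] <- 0
    rest <- n_celltypes - k
    cortex[seq_len(k)] <- 0.01
    cortex[(k + 1):n_celltypes] <- (1 - 0.01 * k) / rest
  } else {
    cortex[seq_len(k)] <- glom[seq_len(k)]
  }
  glom <- glom / sum(glom)
  cortex <- cortex / sum(cortex)
  mix <- rbind(glomeruli = glom, cortex = cortex)
  colnames(mix) <- paste0("ct", seq_len(n_celltypes))
  mix
}

# Shared seed-derived gene universe: baselines, mito flags, cell-type
# signatures and the marker/decoy table. Both generators call this with the
# same config so bulk mixtures and nucleus profiles agree gene-by-gene.
sim_universe <- function(config) {
  set.seed(config$seed)
  n_genes <- config$n_genes
  n_ct <- config$n_celltypes
  n_mito <- round(config$mito_gene_fraction * n_genes)
  gene_ids <- sprintf("gene%05d", seq_len(n_genes))
  is_mito <- rep(FALSE, n_genes)
  if (n_mito > 0) {
    mito_idx <- seq_len(n_mito)  # deterministic: first genes are mt-
    is_mito[mito_idx] <- TRUE
    gene_ids[mito_idx] <- sprintf("mt-gene%05d", mito_idx)
  }
  baseline <- exp(stats::rnorm(n_genes, config$baseline_logmean_mu,
                               config$baseline_logmean_sd))
  celltypes <- colnames(config$compartment_mix)
  # marker planting: round-robin over cell types, non-mito genes only
  plantable <- which(!is_mito & baseline >= config$marker_min_baseline)
  n_marker <- round(config$marker_fraction * n_genes)
  n_decoy <- round(config$decoy_fraction * n_genes)
  n_lineage <- round(config$lineage_marker_fraction * n_genes)
  n_marker <- min(n_marker, length(plantable))
  picked <- if (n_marker + n_decoy + n_lineage > 0) {
    sample(plantable, min(n_marker + n_decoy + n_lineage, length(plantable)))
  } else integer(0)
  marker_idx <- picked[seq_len(min(n_marker, length(picked)))]
  decoy_idx <- picked[seq_len(min(n_marker + n_decoy, length(picked)))][-seq_len(min(n_marker, length(picked)))]
  lineage_idx <- picked[-seq_len(min(n_marker + n_decoy, length(picked)))]
  marker_table <- data.frame(
    gene_id = c(gene_ids[marker_idx], gene_ids[decoy_idx]),
    cell_type = celltypes[1 + (seq_len(length(marker_idx) + length(decoy_idx)) - 1) %% n_ct],
    fold = c(rep(config$marker_fold, length(marker_idx)),
             rep(config$decoy_fold, length(decoy_idx))),
    stringsAsFactors = FALSE
  )
  # lineage programs: fold-up in every cell type of one lineage
  glom_types <- celltypes[seq_len(min(3L, n_ct))]
  tub_types <- setdiff(celltypes, glom_types)
  lineage_of <- if (length(tub_types)) {
    rep_len(c("glomerular", "tubular"), length(lineage_idx))
  } else rep_len("glomerular", length(lineage_idx))
  lineage_table <- data.frame(
    gene_id = gene_ids[lineage_idx], lineage = lineage_of,
    fold = rep(config$lineage_marker_fold, length(lineage_idx)),
    stringsAsFactors = FALSE
  )
  # signatures: baseline, multiplied by fold in the planted cell type(s)
  signatures <- matrix(baseline, nrow = n_genes, ncol = n_ct,
                       dimnames = list(gene_ids, celltypes))
  if (nrow(marker_table) > 0) {
    gi <- match(marker_table$gene_id, gene_ids)
    ci <- match(marker_table$cell_type, celltypes)
    signatures[cbind(gi, ci)] <- baseline[gi] * marker_table$fold
  }
  if (nrow(lineage_table) > 0) {
    for (ln in unique(lineage_table$lineage)) {
      tys <- if (ln == "glomerular") glom_types else tub_types
      gi <- match(lineage_table$gene_id[lineage_table$lineage == ln], gene_ids)
      signatures[gi, tys] <- signatures[gi, tys] * config$lineage_marker_fold
    }
  }
  signatures[is_mito, ] <- 0  # nuclei carry no mitochondrial transcripts
  list(gene_ids = gene_ids, is_mito = is_mito, baseline = baseline,
       signatures = signatures, marker_table = marker_table,
       lineage_table = lineage_table, celltypes = celltypes)
}

rnbinom_mu <- function(n, mu, dispersion) {
  if (dispersion <= 0) stats::rpois(n, mu) else {
    stats::rnbinom(n, mu = mu, size = 1 / dispersion)
  }
}

#' Simulate the paired bulk compartment cohort
#'
#' Generates negative-binomial gene-by-sample count matrices for the
#' glomerular and cortical compartments under the configured group design,
#' with planted differentially expressed genes, log-normal library-size
#' variation and a shared gene universe, together with the ground truth
#' needed to score recovery downstream.
#'
#' Expected means per compartment are the cell-type signature mixture under
#' that compartment's weights; planted DEGs multiply the mean of their
#' (group, compartment) cell by a fold drawn from `deg_fold_range` with
#' random direction.
#'
#' @param config a [sim_config()].
#' @return a list with elements `counts_glomeruli`, `counts_cortex`
#'   (integer matrices, genes x samples), `sample_table` (sample_id, group,
#'   compartment, animal_id), `gene_annotation` (gene_id, length_bp,
#'   is_mito), and `truth` (class `ground_truth`).
#' @export
simulate_bulk <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  uni <- sim_universe(config)
  set.seed(config$seed + 1L)
  groups <- config$groups
  npg <- config$n_per_group
  compartments <- rownames(config$compartment_mix)
  # compartment-level expected means: signature mixture
  comp_mean <- uni$signatures %*% t(config$compartment_mix)  # genes x 2
  # mitochondrial genes are expressed in bulk tissue (whole cells):
  comp_mean[uni$is_mito, ] <- uni$baseline[uni$is_mito]

  sample_table <- expand.grid(
    replicate = seq_len(npg), group = groups, compartment = compartments,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  sample_table$animal_id <- paste0(gsub("[^A-Za-z0-9]+", "", sample_table$group),
                                   "_", sample_table$replicate)
  sample_table$sample_id <- paste0(
    ifelse(sample_table$compartment == "glomeruli", "glom", "cortex"),
    "_", sample_table$animal_id
  )
  sample_table <- sample_table[, c("sample_id", "group", "compartment",
                                   "animal_id")]

  # planted DEGs per (non-reference group, compartment)
  n_deg <- round(config$deg_fraction * config$n_genes)
  if (config$deg_fraction > 0 && n_deg < 1) {
    if (config$strict_deg_rounding) {
      stop("deg_fraction > 0 but rounds to zero planted genes")
    }
    n_deg <- 1L
  }
  deg_rows <- list()
  if (config$deg_fraction > 0) {
    for (comp in compartments) {
      for (grp in groups[-1]) {
        idx <- sample(which(!uni$is_mito), n_deg)
        fold <- stats::runif(n_deg, config$deg_fold_range[1],
                             config$deg_fold_range[2])
        up <- sample(c(TRUE, FALSE), n_deg, replace = TRUE)
        fold <- ifelse(up, fold, 1 / fold)
        deg_rows[[paste(comp, grp)]] <- data.frame(
          gene_id = uni$gene_ids[idx], contrast = paste0(grp, "_vs_", groups[1]),
          compartment = comp, fold_change = fold, stringsAsFactors = FALSE
        )
      }
    }
  }
  deg_table <- if (length(deg_rows)) do.call(rbind, deg_rows) else {
    data.frame(gene_id = character(), contrast = character(),
               compartment = character(), fold_change = numeric(),
               stringsAsFactors = FALSE)
  }
  rownames(deg_table) <- NULL

  lib_factor <- exp(stats::rnorm(nrow(sample_table), 0, config$lib_size_sd))
  names(lib_factor) <- sample_table$sample_id

  mats <- list()
  for (comp in compartments) {
    st <- sample_table[sample_table$compartment == comp, ]
    mu_group <- matrix(comp_mean[, comp], nrow = config$n_genes,
                       ncol = length(groups),
                       dimnames = list(uni$gene_ids, groups))
    dt <- deg_table[deg_table$compartment == comp, ]
    if (nrow(dt)) {
      grp <- sub("_vs_.*$", "", dt$contrast)
      mu_group[cbind(match(dt$gene_id, uni$gene_ids), match(grp, groups))] <-
        mu_group[cbind(match(dt$gene_id, uni$gene_ids), match(grp, groups))] *
        dt$fold_change
    }
    counts <- matrix(0L, config$n_genes, nrow(st),
                     dimnames = list(uni$gene_ids, st$sample_id))
    for (j in seq_len(nrow(st))) {
      mu_j <- mu_group[, st$group[j]] * lib_factor[st$sample_id[j]]
      counts[, j] <- rnbinom_mu(config$n_genes, mu_j, config$dispersion)
    }
    mats[[comp]] <- counts
  }

  gene_annotation <- data.frame(
    gene_id = uni$gene_ids,
    length_bp = round(exp(stats::rnorm(config$n_genes, log(2000), 0.5))),
    is_mito = uni$is_mito, stringsAsFactors = FALSE
  )

  truth <- structure(list(
    deg_table = deg_table,
    marker_table = uni$marker_table,
    lineage_table = uni$lineage_table,
    nucleus_qc_table = data.frame(barcode = character(),
                                  true_mito_fraction = numeric(),
                                  keep = logical(), stringsAsFactors = FALSE),
    mixing_weights = config$compartment_mix,
    lib_factors = lib_factor
  ), class = "ground_truth")

  list(counts_glomeruli = mats[["glomeruli"]],
       counts_cortex = mats[["cortex"]],
       sample_table = sample_table,
       gene_annotation = gene_annotation,
       truth = truth)
}

#' Simulate the labelled single-nucleus matrix
#'
#' Draws per-nucleus counts (Poisson, or NB when `sn_dispersion > 0`) from
#' the cell-type signatures of the shared gene universe, over
#' `n_celltypes x n_nuclei_per_type` nuclei. Planted markers have expected
#' fold `marker_fold` over every other cell type. A `mito_high_fraction`
#' of nuclei carries a true mitochondrial fraction of `mito_high_level`
#' (above the 0.25% QC threshold); all other nuclei have zero expected
#' mitochondrial signal, as expected of nuclear RNA.
#'
#' @param config a [sim_config()].
#' @return list with `counts` (dgCMatrix genes x nuclei), `labels`
#'   (barcode, cell_type, animal_id), `gene_annotation`, and `truth`
#'   (ground truth with populated `nucleus_qc_table`).
#' @export
simulate_sn <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_celltypes < 2) stop("simulate_sn requires n_celltypes >= 2")
  uni <- sim_universe(config)
  set.seed(config$seed + 2L)
  n_ct <- config$n_celltypes
  n_nuc <- n_ct * config$n_nuclei_per_type
  barcodes <- sprintf("nuc%06d", seq_len(n_nuc))
  cell_type <- rep(uni$celltypes, each = config$n_nuclei_per_type)
  animals <- c("dbm_1", "UNxRenin_1", "UNxRenin_2")
  animal_id <- sample(animals, n_nuc, replace = TRUE)

  sig_sum <- colSums(uni$signatures)
  lib <- config$nucleus_lib_size * exp(stats::rnorm(n_nuc, 0, config$sn_lib_size_sd))
  high <- stats::runif(n_nuc) < config$mito_high_fraction
  true_mito <- ifelse(high, config$mito_high_level, 0)

  mito_idx <- which(uni$is_mito)
  mito_weights <- if (length(mito_idx)) {
    w <- uni$baseline[mito_idx]
    w / sum(w)
  } else numeric(0)

  # build sparse triplets column by column
  ilist <- vector("list", n_nuc)
  xlist <- vector("list", n_nuc)
  for (j in seq_len(n_nuc)) {
    sig <- uni$signatures[, cell_type[j]]
    mu <- sig / sig_sum[cell_type[j]] * lib[j] * (1 - true_mito[j])
    if (true_mito[j] > 0 && length(mito_idx)) {
      mu[mito_idx] <- mito_weights * lib[j] * true_mito[j]
    }
    cnt <- rnbinom_mu(config$n_genes, mu, config$sn_dispersion)
    nz <- which(cnt > 0L)
    ilist[[j]] <- nz
    xlist[[j]] <- cnt[nz]
  }
  nnz <- lengths(ilist)
  counts <- Matrix::sparseMatrix(
    i = unlist(ilist), j = rep.int(seq_len(n_nuc), nnz), x = unlist(xlist),
    dims = c(config$n_genes, n_nuc),
    dimnames = list(uni$gene_ids, barcodes)
  )

  labels <- data.frame(barcode = barcodes, cell_type = cell_type,
                       animal_id = animal_id, stringsAsFactors = FALSE)
  nucleus_qc <- data.frame(barcode = barcodes, true_mito_fraction = true_mito,
                           keep = true_mito <= 0.0025,
                           stringsAsFactors = FALSE)
  gene_annotation <- data.frame(gene_id = uni$gene_ids,
                                length_bp = NA_integer_,
                                is_mito = uni$is_mito,
                                stringsAsFactors = FALSE)
  truth <- structure(list(
    deg_table = data.frame(gene_id = character(), contrast = character(),
                           compartment = character(), fold_change = numeric(),
                           stringsAsFactors = FALSE),
    marker_table = uni$marker_table,
    lineage_table = uni$lineage_table,
    nucleus_qc_table = nucleus_qc,
    mixing_weights = config$compartment_mix,
    lib_factors = stats::setNames(lib, barcodes)
  ), class = "ground_truth")

  list(counts = counts, labels = labels, gene_annotation = gene_annotation,
       truth = truth)
}

#' Write ground truth tables to TSV
#'
#' Writes `deg_table.tsv`, `marker_table.tsv`, `nucleus_qc_table.tsv` and
#' `mixing_weights.tsv` under `dir`; [read_truth()] restores them
#' losslessly.
#'
#' @param truth a `ground_truth` object.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "ground_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir)
  paths <- c(
    deg_table = file.path(dir, "deg_table.tsv"),
    marker_table = file.path(dir, "marker_table.tsv"),
    lineage_table = file.path(dir, "lineage_table.tsv"),
    nucleus_qc_table = file.path(dir, "nucleus_qc_table.tsv"),
    mixing_weights = file.path(dir, "mixing_weights.tsv")
  )
  write_tsv_plain(truth$deg_table, paths["deg_table"])
  write_tsv_plain(truth$marker_table, paths["marker_table"])
  write_tsv_plain(truth$lineage_table, paths["lineage_table"])
  write_tsv_plain(truth$nucleus_qc_table, paths["nucleus_qc_table"])
  mw <- data.frame(compartment = rownames(truth$mixing_weights),
                   truth$mixing_weights, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_plain(mw, paths["mixing_weights"])
  invisible(paths)
}

#' Read ground truth tables written by [write_truth()]
#' @param dir directory containing the truth TSVs.
#' @return a `ground_truth` object.
#' @export
read_truth <- function(dir) {
  deg <- read_tsv_plain(file.path(dir, "deg_table.tsv"),
                        c(gene_id = "character", contrast = "character",
                          compartment = "character", fold_change = "numeric"))
  mk <- read_tsv_plain(file.path(dir, "marker_table.tsv"),
                       c(gene_id = "character", cell_type = "character",
                         fold = "numeric"))
  ln <- read_tsv_plain(file.path(dir, "lineage_table.tsv"),
                       c(gene_id = "character", lineage = "character",
                         fold = "numeric"))
  qc <- read_tsv_plain(file.path(dir, "nucleus_qc_table.tsv"),
                       c(barcode = "character",
                         true_mito_fraction = "numeric", keep = "logical"))
  mw <- utils::read.delim(file.path(dir, "mixing_weights.tsv"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  weights <- as.matrix(mw[, -1, drop = FALSE])
  rownames(weights) <- mw$compartment
  structure(list(deg_table = deg, marker_table = mk, lineage_table = ln,
                 nucleus_qc_table = qc,
                 mixing_weights = weights),
            class = "ground_truth")
}
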