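#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median, over reference
#' genes, of the ratio of each sample's count to the gene's geometric mean
#' across samples, then rescaled to geometric mean 1. Reference genes are
#' those with a nonzero count in every sample; when none exists, a
#' pseudo-reference over genes expressed in at least half the samples can be
#' used instead.
#'
#' @param counts integer matrix, genes x samples (rownames gene ids).
#' @param pseudo_reference fall back to a pseudo-reference (genes expressed
#'   in >= half the samples, geometric mean over their nonzero entries) when
#'   no gene is expressed in all samples.
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts, pseudo_reference = FALSE) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 1 || nrow(counts) < 1) stop("empty count matrix")
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos)) {
    if (!pseudo_reference) {
      stop("no gene has nonzero counts in every sample; ",
           "rerun with pseudo_reference = TRUE to normalize against a ",
           "pseudo-reference built from genes expressed in >= half the samples")
    }
    half <- rowSums(counts > 0) >= ncol(counts) / 2
    if (!any(half)) stop("no gene expressed in at least half the samples")
    message("size_factors: using pseudo-reference over ", sum(half),
            " genes expressed in >= half the samples")
    sub <- counts[half, , drop = FALSE]
    ref <- apply(sub, 1, function(x) exp(mean(log(x[x > 0]))))
    f <- apply(sub, 2, function(x) {
      ok <- x > 0
      stats::median(x[ok] / ref[ok])
    })
  } else {
    sub <- counts[all_pos, , drop = FALSE]
    ref <- exp(rowMeans(log(sub)))
    f <- apply(sub / ref, 2, stats::median)
  }
  f <- f / exp(mean(log(f)))  # geometric mean 1
  stats::setNames(f, colnames(counts))
}

#' Reads per kilobase of transcript per million mapped reads
#'
#' `rpkm_gj = count_gj * 1e9 / (length_g * total_counts_j)`, normalizing for
#' transcript length and sequencing depth.
#'
#' @param counts genes x samples count matrix.
#' @param gene_lengths positive lengths in bp, one per gene (named or in row
#'   order).
#' @return matrix of RPKM values with the dimensions of `counts`.
#' @export
rpkm <- function(counts, gene_lengths) {
  counts <- as.matrix(counts)
  if (missing(gene_lengths) || is.null(gene_lengths)) {
    stop("gene_lengths are required for RPKM")
  }
  if (!is.null(names(gene_lengths)) && !is.null(rownames(counts))) {
    gene_lengths <- gene_lengths[rownames(counts)]
  }
  if (length(gene_lengths) != nrow(counts) || any(!is.finite(gene_lengths)) ||
      any(gene_lengths <= 0)) {
    stop("gene_lengths must be positive and match the gene dimension")
  }
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("samples with zero total counts")
  sweep(counts / gene_lengths, 2, lib, "/") * 1e9
}

#' Method-of-moments dispersion estimates with trend shrinkage
#'
#' Per-gene NB dispersion on size-factor-normalized counts: within each
#' group the moment estimate `(s^2 - m) / m^2` is computed and pooled across
#' groups weighted by degrees of freedom, floored at zero; the pooled
#' estimate is then shrunk toward a log-linear mean-dispersion trend by a
#' weighted average.
#'
#' @param counts genes x samples count matrix.
#' @param groups group label per sample (each group needs >= 2 samples).
#' @param sf size factors; computed by [size_factors()] when `NULL`.
#' @param shrink_weight weight on the trend value in `[0, 1]`.
#' @param floor lower bound applied to the final estimate.
#' @return data.frame with columns `gene_id`, `base_mean`, `alpha_mom`,
#'   `alpha_trend`, `alpha`.
#' @export
estimate_dispersions <- function(counts, groups, sf = NULL,
                                 shrink_weight = 0.5, floor = 1e-8) {
  counts <- as.matrix(counts)
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(counts), shrink_weight >= 0,
            shrink_weight <= 1)
  tab <- table(groups)
  if (any(tab < 2)) {
    stop("each group needs at least 2 samples for dispersion estimation")
  }
  if (is.null(sf)) sf <- size_factors(counts, pseudo_reference = TRUE)
  norm <- sweep(counts, 2, sf, "/")
  num <- 0; den <- 0
  for (g in names(tab)) {
    sub <- norm[, groups == g, drop = FALSE]
    m <- rowMeans(sub)
    v <- apply(sub, 1, stats::var)
    a_g <- ifelse(m > 0, (v - m) / m^2, 0)
    num <- num + (ncol(sub) - 1) * a_g
    den <- den + (ncol(sub) - 1)
  }
  alpha_mom <- pmax(0, num / den)
  base_mean <- rowMeans(norm)
  # log-linear trend alpha ~ mean, fitted on informative genes
  ok <- alpha_mom > 0 & base_mean > 0
  if (sum(ok) >= 10) {
    df <- data.frame(la = log(alpha_mom[ok]), lmean = log(base_mean[ok]))
    fit <- stats::lm(la ~ lmean, data = df)
    alpha_trend <- rep(exp(mean(df$la)), length(alpha_mom))
    pos <- base_mean > 0
    alpha_trend[pos] <- exp(stats::predict(
      fit, newdata = data.frame(lmean = log(base_mean[pos]))))
  } else {
    alpha_trend <- rep(max(stats::median(alpha_mom), floor), length(alpha_mom))
  }
  alpha <- pmax(floor, (1 - shrink_weight) * alpha_mom +
                  shrink_weight * alpha_trend)
  data.frame(gene_id = rownames(counts), base_mean = base_mean,
             alpha_mom = alpha_mom, alpha_trend = alpha_trend,
             alpha = alpha, row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; monotone in rank and capped
#' at 1. Rejects missing or out-of-range p-values.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (anyNA(pvals)) stop("bh_adjust: NA/NaN p-values are not allowed")
  if (any(pvals < 0 | pvals > 1)) stop("bh_adjust: p-values outside [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

# Vectorized IRLS for the per-gene NB GLM with log link,
# design = intercept + group indicator, offset = log size factor.
# Returns per-gene beta (natural log), se of the group effect, convergence.
nb_irls <- function(y, x, log_sf, alpha, max_iter = 50, tol = 1e-8) {
  n <- ncol(y)
  m0 <- rowMeans(sweep(y[, x == 0, drop = FALSE], 2,
                       exp(log_sf[x == 0]), "/"))
  m1 <- rowMeans(sweep(y[, x == 1, drop = FALSE], 2,
                       exp(log_sf[x == 1]), "/"))
  b0 <- log(pmax(m0, 1e-8))
  b1 <- log(pmax(m1, 1e-8)) - b0
  conv <- rep(FALSE, nrow(y))
  active <- rep(TRUE, nrow(y))
  A11 <- A12 <- det <- rep(NA_real_, nrow(y))
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    idx <- which(active)
    eta <- outer(b0[idx], rep(1, n)) + outer(b1[idx], x) +
      matrix(log_sf, length(idx), n, byrow = TRUE)
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + alpha[idx] * mu)
    z <- (eta - matrix(log_sf, length(idx), n, byrow = TRUE)) +
      (y[idx, , drop = FALSE] - mu) / mu
    a11 <- rowSums(w)
    a12 <- rowSums(w[, x == 1, drop = FALSE])
    r1 <- rowSums(w * z)
    r2 <- rowSums((w * z)[, x == 1, drop = FALSE])
    d <- a11 * a12 - a12^2
    bad <- !is.finite(d) | d <= 1e-12
    nb0 <- ifelse(bad, b0[idx], (a12 * r1 - a12 * r2) / pmax(d, 1e-300))
    nb1 <- ifelse(bad, b1[idx], (a11 * r2 - a12 * r1) / pmax(d, 1e-300))
    # cap steps to keep eta in range
    nb0 <- pmin(pmax(nb0, -30), 30)
    nb1 <- pmin(pmax(nb1, -60), 60)
    delta <- pmax(abs(nb0 - b0[idx]), abs(nb1 - b1[idx]))
    b0[idx] <- nb0; b1[idx] <- nb1
    A11[idx] <- a11; A12[idx] <- a12; det[idx] <- d
    done <- delta < tol & !bad
    conv[idx[done]] <- TRUE
    active[idx[done]] <- FALSE
  }
  se <- sqrt(ifelse(is.finite(det) & det > 0, A11 / det, NA_real_))
  list(beta0 = b0, beta1 = b1, se1 = se, converged = conv)
}

#' Negative-binomial Wald differential expression test
#'
#' Fits, per gene, an NB generalized linear model with log link, an offset
#' of log size factor, and a design of intercept plus group indicator, and
#' tests the group coefficient with a Wald z statistic against the standard
#' normal. P-values are Benjamini-Hochberg adjusted over the tested genes.
#' Genes below the independent-filtering threshold on mean normalized count
#' are excluded from the BH family and reported with adjusted p of 1;
#' all-zero genes are excluded from testing and reported with p of 1.
#' Numerically failed fits fall back to a moment-based z with a message.
#'
#' @param counts genes x samples count matrix.
#' @param sample_table data.frame with columns `sample_id` and `group`
#'   covering the columns of `counts`.
#' @param contrast length-2 character: `c(test_group, reference_group)`;
#'   log2 fold-changes are test over reference.
#' @param dispersions optional per-gene dispersions (vector named by gene or
#'   the data.frame of [estimate_dispersions()]); estimated internally when
#'   `NULL`.
#' @param sf optional size factors; computed from the contrast's samples
#'   when `NULL`.
#' @param alpha DEG significance level on adjusted p (strict `<`).
#' @param filter_threshold independent-filtering threshold on mean
#'   normalized count.
#' @return data.frame of class `de_result`: `gene_id`, `base_mean`,
#'   `log2fc`, `lfc_se`, `stat`, `pvalue`, `padj`, `is_deg`, `tested`.
#' @export
nb_wald_test <- function(counts, sample_table, contrast,
                         dispersions = NULL, sf = NULL,
                         alpha = 0.05, filter_threshold = 1) {
  counts <- as.matrix(counts)
  stopifnot(length(contrast) == 2,
            all(c("sample_id", "group") %in% names(sample_table)))
  if (!all(contrast %in% sample_table$group)) {
    stop("both contrast groups must be present in sample_table")
  }
  st <- sample_table[sample_table$group %in% contrast, ]
  st <- st[st$sample_id %in% colnames(counts), ]
  if (any(table(st$group) < 2)) stop("each contrast group needs >= 2 samples")
  y <- counts[, st$sample_id, drop = FALSE]
  x <- as.numeric(st$group == contrast[1])
  if (is.null(sf)) sf <- size_factors(y, pseudo_reference = TRUE)
  sf <- sf[st$sample_id]
  if (is.null(dispersions)) {
    dispersions <- estimate_dispersions(y, st$group, sf = sf)
  }
  if (is.data.frame(dispersions)) {
    disp <- stats::setNames(dispersions$alpha, dispersions$gene_id)[rownames(y)]
  } else if (!is.null(names(dispersions))) {
    disp <- dispersions[rownames(y)]
  } else {
    disp <- rep_len(dispersions, nrow(y))
  }
  disp <- pmax(disp, 1e-8)

  norm <- sweep(y, 2, sf, "/")
  base_mean <- rowMeans(norm)
  nonzero <- rowSums(y) > 0

  log2fc <- lfc_se <- stat <- pvalue <- rep(NA_real_, nrow(y))
  log2fc[!nonzero] <- 0
  stat[!nonzero] <- 0
  pvalue[!nonzero] <- 1

  if (any(nonzero)) {
    fit <- nb_irls(y[nonzero, , drop = FALSE], x, log(sf), disp[nonzero])
    b1 <- fit$beta1; se <- fit$se1
    failed <- !fit$converged | !is.finite(b1) | !is.finite(se) | se <= 0
    if (any(failed)) {
      message("nb_wald_test: ", sum(failed),
              " gene(s) fell back to moment-based z after IRLS failure")
      sub <- norm[nonzero, , drop = FALSE][failed, , drop = FALSE]
      m0 <- rowMeans(sub[, x == 0, drop = FALSE])
      m1 <- rowMeans(sub[, x == 1, drop = FALSE])
      a <- disp[nonzero][failed]
      n0 <- sum(x == 0); n1 <- sum(x == 1)
      eps <- 0.5
      b1[failed] <- log((m1 + eps) / (m0 + eps))
      v0 <- (m0 + a * m0^2) / (n0 * (m0 + eps)^2)
      v1 <- (m1 + a * m1^2) / (n1 * (m1 + eps)^2)
      se[failed] <- sqrt(pmax(v0 + v1, 1e-12))
    }
    z <- b1 / se
    log2fc[nonzero] <- b1 / log(2)
    lfc_se[nonzero] <- se / log(2)
    stat[nonzero] <- z
    pvalue[nonzero] <- 2 * stats::pnorm(-abs(z))
  }

  tested <- nonzero & base_mean >= filter_threshold
  padj <- rep(1, nrow(y))
  if (any(tested)) padj[tested] <- bh_adjust(pvalue[tested])
  res <- data.frame(
    gene_id = rownames(y), base_mean = base_mean, log2fc = log2fc,
    lfc_se = lfc_se, stat = stat, pvalue = pvalue, padj = padj,
    is_deg = padj < alpha, tested = tested,
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(res, "contrast") <- contrast
  attr(res, "alpha") <- alpha
  class(res) <- c("de_result", "data.frame")
  res
}

#' DEG call at a significance level
#'
#' Genes with adjusted p strictly below `alpha` (default 0.05).
#'
#' @param result a `de_result` from [nb_wald_test()].
#' @param alpha significance level on adjusted p.
#' @return character vector of DEG gene ids.
#' @export
call_degs <- function(result, alpha = 0.05) {
  stopifnot(all(c("gene_id", "padj") %in% names(result)))
  result$gene_id[result$padj < alpha]
}
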