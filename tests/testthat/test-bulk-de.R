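test_that("size factors satisfy forced identities", {
  m <- tiny_counts(30, 4)
  same <- cbind(m[, 1], m[, 1], m[, 1])
  colnames(same) <- paste0("s", 1:3)
  expect_equal(unname(size_factors(same)), rep(1, 3))
  two <- cbind(a = m[, 1] + 1L, b = 2L * (m[, 1] + 1L))
  expect_equal(unname(size_factors(two)), c(1 / sqrt(2), sqrt(2)))
})

test_that("size factors equal the brute-force median-of-ratios", {
  set.seed(21)
  m <- matrix(rpois(200, 40) + 1L, 50, 4,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:4)))
  expect_equal(unname(size_factors(m)), unname(size_factors_brute(m)),
               tolerance = 1e-12)
})

test_that("size factors recover simulated library scalings", {
  cfg <- sim_config(n_genes = 2000, n_per_group = 6, seed = 13)
  b <- simulate_bulk(cfg)
  sf <- size_factors(b$counts_cortex)
  truth <- b$truth$lib_factors[names(sf)]
  truth <- truth / exp(mean(log(truth)))
  expect_lte(median(abs(sf - truth) / truth), 0.05)
})

test_that("size factor fallback needs opting in and a usable reference", {
  m <- rbind(g1 = c(0L, 5L, 7L), g2 = c(4L, 0L, 6L), g3 = c(3L, 8L, 0L))
  colnames(m) <- paste0("s", 1:3)
  expect_error(size_factors(m), "pseudo_reference")
  expect_message(sf <- size_factors(m, pseudo_reference = TRUE),
                 "pseudo-reference")
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-12)
})

test_that("rpkm follows its defining formula", {
  cnt <- matrix(c(10L, 999990L), 2, 1,
                dimnames = list(c("a", "b"), "s1"))
  r <- rpkm(cnt, c(a = 1000, b = 50000))
  expect_equal(r["a", 1], 10)  # 10 reads, 1 kb, 1e6 library
  zero <- matrix(c(0L, 100L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(rpkm(zero, c(a = 500, b = 500))["a", 1], 0)
  set.seed(4)
  m <- matrix(rpois(60, 30), 20, 3,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%d", 1:3)))
  len <- setNames(sample(200:5000, 20), rownames(m))
  expect_equal(rpkm(m, len), rpkm_brute(m, len), tolerance = 1e-12)
  expect_error(rpkm(m, NULL), "required")
})

test_that("dispersion estimation recovers known truth", {
  set.seed(31)
  # Poisson data: true alpha = 0
  m <- matrix(rpois(500 * 40, 100), 500, 40,
              dimnames = list(sprintf("g%03d", 1:500), sprintf("s%02d", 1:40)))
  grp <- rep(c("A", "B"), each = 20)
  d <- estimate_dispersions(m, grp, sf = rep(1, 40), shrink_weight = 0)
  expect_lte(median(d$alpha), 0.01)
  # NB with alpha = 0.1 at mean 100, n = 50 per group
  m2 <- matrix(rnbinom(500 * 100, mu = 100, size = 10), 500, 100,
               dimnames = list(sprintf("g%03d", 1:500), sprintf("s%03d", 1:100)))
  grp2 <- rep(c("A", "B"), each = 50)
  d2 <- estimate_dispersions(m2, grp2, sf = rep(1, 100))
  expect_gte(median(d2$alpha), 0.05)
  expect_lte(median(d2$alpha), 0.2)
  # constant counts within groups: moment estimate floored
  m3 <- matrix(7L, 10, 4, dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  d3 <- estimate_dispersions(m3, c("A", "A", "B", "B"), sf = rep(1, 4),
                             shrink_weight = 0)
  expect_true(all(d3$alpha_mom == 0))
  expect_true(all(d3$alpha >= 1e-8))
  expect_error(estimate_dispersions(m3, c("A", "A", "A", "B")), "2 samples")
})

test_that("Wald test identities: constant genes, swapped contrasts", {
  set.seed(41)
  m <- matrix(rnbinom(200 * 12, mu = 60, size = 10), 200, 12,
              dimnames = list(sprintf("g%03d", 1:200), sprintf("s%02d", 1:12)))
  m[1, ] <- 50L                     # identical in every sample
  m[2, ] <- 0L                      # all-zero row
  st <- data.frame(sample_id = colnames(m),
                   group = rep(c("ctl", "trt"), each = 6))
  sf1 <- setNames(rep(1, 12), colnames(m))
  res <- nb_wald_test(m, st, c("trt", "ctl"), sf = sf1)
  expect_equal(res$log2fc[res$gene_id == "g001"], 0, tolerance = 1e-10)
  expect_equal(res$pvalue[res$gene_id == "g002"], 1)
  expect_false(res$tested[res$gene_id == "g002"])
  # swapped contrast: negated log2FC, identical p
  swap <- nb_wald_test(m, st, c("ctl", "trt"), sf = sf1)
  expect_equal(swap$log2fc, -res$log2fc, tolerance = 1e-6)
  expect_equal(swap$pvalue, res$pvalue, tolerance = 1e-8)
})

test_that("Wald results agree with an established NB GLM fitter", {
  skip_if_not_installed("DESeq2")
  set.seed(51)
  m <- matrix(rnbinom(300 * 16, mu = 80, size = 10), 300, 16,
              dimnames = list(sprintf("g%03d", 1:300), sprintf("s%02d", 1:16)))
  st <- data.frame(sample_id = colnames(m),
                   group = rep(c("ctl", "trt"), each = 8))
  alpha_fixed <- setNames(rep(0.1, 300), rownames(m))
  sf1 <- setNames(rep(1, 16), colnames(m))
  res <- nb_wald_test(m, st, c("trt", "ctl"), dispersions = alpha_fixed,
                      sf = sf1)
  dds <- DESeq2::DESeqDataSetFromMatrix(
    m, data.frame(group = factor(rep(c("ctl", "trt"), each = 8),
                                 levels = c("ctl", "trt"))), ~group)
  DESeq2::sizeFactors(dds) <- rep(1, 16)
  DESeq2::dispersions(dds) <- rep(0.1, 300)
  dds <- DESeq2::nbinomWaldTest(dds)
  ref <- DESeq2::results(dds, contrast = c("group", "trt", "ctl"))
  expect_gt(cor(res$log2fc, ref$log2FoldChange), 0.999)
  expect_lt(median(abs(res$log2fc - ref$log2FoldChange)), 0.01)
  expect_gt(cor(res$stat, ref$stat), 0.999)
})

test_that("independent filtering excludes weak genes from the BH family", {
  set.seed(61)
  m <- matrix(rnbinom(100 * 8, mu = 30, size = 10), 100, 8,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("s%d", 1:8)))
  m[1:10, ] <- matrix(rbinom(80, 1, 0.3), 10, 8)  # mean < 1
  st <- data.frame(sample_id = colnames(m),
                   group = rep(c("A", "B"), each = 4))
  res <- nb_wald_test(m, st, c("B", "A"), sf = setNames(rep(1, 8), colnames(m)))
  weak <- res$base_mean < 1 & rowSums(m) > 0
  expect_true(all(!res$tested[weak]))
  expect_true(all(res$padj[weak] == 1))
  expect_equal(res$padj[res$tested],
               bh_brute(res$pvalue[res$tested]), tolerance = 1e-12)
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_adjust(0.037), 0.037)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(bh_adjust(c(0.1, NaN)), "NA/NaN")
  expect_error(bh_adjust(c(0.1, 1.2)), "outside")
  set.seed(71)
  for (i in 1:50) {
    p <- runif(sample(1:200, 1))
    a <- bh_adjust(p)
    expect_equal(a, bh_brute(p), tolerance = 1e-12)
    expect_true(all(a >= p))
    expect_true(all(a <= 1))
  }
})

test_that("DEG calls use strict inequality at the threshold", {
  de <- fake_de(c(0.5, 0.5, 0.5))
  de$padj <- c(0.049999, 0.05, 1)
  expect_equal(call_degs(de, 0.05), "g0001")
  de$padj <- rep(1, 3)
  expect_equal(call_degs(de), character(0))
})
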