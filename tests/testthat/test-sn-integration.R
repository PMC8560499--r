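make_sn_matrix <- function(mito_counts, other_counts) {
  # 2 mito genes + 3 ordinary genes, one nucleus per column
  n <- length(mito_counts)
  m <- rbind(
    matrix(c(mito_counts, rep(0, n)), nrow = 2, byrow = TRUE),
    matrix(rep(other_counts, each = 3) / 3, nrow = 3)
  )
  rownames(m) <- c("mt-a", "mt-b", "g1", "g2", "g3")
  colnames(m) <- sprintf("bc%02d", seq_len(n))
  Matrix::Matrix(round(m), sparse = TRUE)
}

test_that("mitochondrial filter applies the strict 0.25% rule", {
  # fractions: 0.1% (keep), 0.3% (remove), exactly 0.25% (keep: strict >)
  m <- make_sn_matrix(c(1, 3, 1), c(999, 997, 399))
  is_mito <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  names(is_mito) <- rownames(m)
  out <- filter_nuclei_mito(m, is_mito)
  expect_equal(colnames(out), c("bc01", "bc03"))
  expect_equal(attr(out, "removed_barcodes"), "bc02")
})

test_that("zero-count nuclei are removed and unflagged matrices pass through", {
  m <- make_sn_matrix(c(0, 0), c(900, 0))
  is_mito <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_message(out <- filter_nuclei_mito(m, is_mito), "zero total")
  expect_equal(ncol(out), 1)
  expect_warning(noop <- filter_nuclei_mito(m, rep(FALSE, 5)), "no-op")
  expect_equal(ncol(noop), 2)
})

test_that("filter agrees exactly with generator ground truth", {
  cfg <- sim_config(n_genes = 500, n_celltypes = 6, n_nuclei_per_type = 60,
                    seed = 17)
  sn <- simulate_sn(cfg)
  out <- filter_nuclei_mito(sn$counts, sn$gene_annotation$is_mito)
  qc <- sn$truth$nucleus_qc_table
  expect_equal(sort(colnames(out)), sort(qc$barcode[qc$keep]))
})

test_that("cell-type profiles equal direct aggregation", {
  set.seed(121)
  m <- Matrix::Matrix(matrix(rpois(100 * 300, 2), 100, 300,
                             dimnames = list(sprintf("g%03d", 1:100),
                                             sprintf("bc%03d", 1:300))),
                      sparse = TRUE)
  labels <- data.frame(barcode = colnames(m),
                       cell_type = sample(c("podo", "pt", "tal"), 300, TRUE))
  for (norm in c("cp10k", "raw")) {
    prof <- celltype_profiles(m, labels, norm = norm)
    oracle <- profiles_brute(m, labels, cp10k = (norm == "cp10k"))
    expect_equal(prof, oracle, tolerance = 1e-12, ignore_attr = TRUE)
  }
  # one nucleus per type: the profile is that nucleus's normalized vector
  lab1 <- data.frame(barcode = c("bc001", "bc002"),
                     cell_type = c("a", "b"))
  prof1 <- celltype_profiles(m, lab1, norm = "cp10k")
  v <- as.numeric(m[, "bc001"]) / sum(m[, "bc001"]) * 1e4
  expect_equal(unname(prof1["a", ]), v, tolerance = 1e-12)
  # duplicated nuclei average to themselves
  m2 <- m[, c(1, 1, 2)]; colnames(m2) <- c("x1", "x2", "y")
  lab2 <- data.frame(barcode = colnames(m2), cell_type = c("a", "a", "b"))
  prof2 <- celltype_profiles(m2, lab2, norm = "raw")
  expect_equal(unname(prof2["a", ]), as.numeric(m[, 1]))
  expect_error(celltype_profiles(m, data.frame(barcode = "nope",
                                               cell_type = "a")),
               "absent")
})

test_that("the twofold specificity rule follows its stated criteria", {
  prof <- rbind(A = c(10, 10, 5, 10, 0.05),
                B = c(4, 6, 0, 10, 0.01),
                C = c(1, 1, 0, 2, 0.01))
  colnames(prof) <- paste0("g", 1:5)
  sm <- assign_specific_genes(prof)
  expect_equal(sm$cell_type[sm$gene_id == "g1"], "A")    # ratio 2.5
  expect_true(is.na(sm$cell_type[sm$gene_id == "g2"]))   # ratio 1.67
  expect_equal(sm$cell_type[sm$gene_id == "g3"], "A")    # runner-up 0
  expect_equal(sm$fold_ratio[sm$gene_id == "g3"], Inf)
  expect_true(is.na(sm$cell_type[sm$gene_id == "g4"]))   # exact top tie
  expect_true(is.na(sm$cell_type[sm$gene_id == "g5"]))   # below min_expr
  expect_equal(assign_specific_genes(prof, min_expr = 0)$cell_type[5], "A")
  # exactly twofold is inclusive
  prof2 <- rbind(A = 4, B = 2)
  colnames(prof2) <- "g"
  expect_equal(assign_specific_genes(prof2, min_expr = 0)$cell_type, "A")
  expect_error(assign_specific_genes(prof2[1, , drop = FALSE]), ">= 2")
})

test_that("specificity is invariant to common rescaling of profiles", {
  set.seed(131)
  prof <- matrix(rexp(8 * 50, 1 / 5), 8, 50,
                 dimnames = list(paste0("ct", 1:8), sprintf("g%02d", 1:50)))
  a <- assign_specific_genes(prof, min_expr = 0)
  b <- assign_specific_genes(prof * 37.5, min_expr = 0)
  expect_equal(a$cell_type, b$cell_type)
  expect_equal(a$fold_ratio, b$fold_ratio, tolerance = 1e-12)
})

test_that("DEG superimposition matches set algebra and conserves counts", {
  spec <- data.frame(
    gene_id = c("nphs1", "nphs2", "slc1", "umod"),
    cell_type = c("podo", "podo", "pt", NA),
    top_cell_type = c("podo", "podo", "pt", "tal"),
    runner_up_cell_type = "x", top_expr = 10, runner_up_expr = 1,
    fold_ratio = 10, stringsAsFactors = FALSE
  )
  s <- superimpose_degs(spec, degs_glom = "nphs1", degs_cortex = character(0))
  podo <- s[s$cell_type == "podo", ]
  expect_equal(podo$glomeruli, 1)
  expect_equal(podo$none, 1)
  expect_equal(podo$n_specific, 2)
  empty <- superimpose_degs(spec, character(0), character(0))
  expect_true(all(empty$none == empty$n_specific))
  # randomized oracle: 500 genes, random DEG membership
  set.seed(141)
  ids <- sprintf("g%04d", 1:500)
  spec2 <- data.frame(gene_id = ids,
                      cell_type = sample(paste0("ct", 1:10), 500, TRUE),
                      top_cell_type = "x", runner_up_cell_type = "y",
                      top_expr = 1, runner_up_expr = 0.1, fold_ratio = 10,
                      stringsAsFactors = FALSE)
  dg <- sample(ids, 120); dc <- sample(ids, 200)
  s2 <- superimpose_degs(spec2, dg, dc)
  for (ct in s2$cell_type) {
    g <- spec2$gene_id[spec2$cell_type == ct]
    row <- s2[s2$cell_type == ct, ]
    expect_equal(row$both, length(intersect(intersect(g, dg), dc)))
    expect_equal(row$glomeruli, length(setdiff(intersect(g, dg), dc)))
    expect_equal(row$cortex, length(setdiff(intersect(g, dc), dg)))
    expect_equal(row$none, length(setdiff(setdiff(g, dg), dc)))
    expect_equal(row$n_specific,
                 row$both + row$glomeruli + row$cortex + row$none)
  }
})

test_that("cell counts per type and animal form the expected contingency", {
  labels <- data.frame(
    barcode = sprintf("b%02d", 1:60),
    cell_type = rep(c("podo", "pt", "tal"), each = 20),
    animal_id = rep(rep(c("m1", "m2"), each = 10), 3)
  )
  tab <- cell_counts_per_type(labels)
  expect_true(all(tab == 10))
  expect_equal(sum(tab), 60)
  one <- cell_counts_per_type(labels[1, ])
  expect_equal(sum(one), 1)
  cfg <- sim_config(n_genes = 100, n_celltypes = 5, n_nuclei_per_type = 30,
                    seed = 23)
  sn <- simulate_sn(cfg)
  tab2 <- cell_counts_per_type(sn$labels)
  expect_equal(unname(rowSums(tab2)), rep(30, 5))
})
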