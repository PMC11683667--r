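# 6 genes x 5 cells toy: g6 detected in only 2 cells, c5 dominated by mito
# counts. Hand enumeration: g6 removed by the gene filter; on the filtered
# matrix every cell still shows 5 detected genes, but c5's mito percent is
# 45/49 = 91.8 so it is removed by the mito criterion alone.
toy_qc_matrix <- function() {
  m <- rbind(
    g1 = c(1, 2, 1, 3, 1),
    g2 = c(2, 1, 4, 1, 1),
    g3 = c(1, 1, 1, 1, 1),
    g4 = c(3, 2, 1, 2, 1),
    g5 = c(5, 4, 2, 1, 45),   # mito gene
    g6 = c(0, 0, 1, 2, 0))    # detected in 2 cells only
  expression_matrix(m, rownames(m), sprintf("c%d", 1:5), "raw_counts")
}

test_that("QC filters match the hand-enumerated toy case", {
  thr <- qc_thresholds(min_cells_per_gene = 2, min_genes_per_cell = 3,
                       gene_count_range = c(1, 100), max_mito_percent = 80)
  out <- apply_qc(toy_qc_matrix(), thr, mito_genes = "g5")
  expect_identical(out$counts$gene_ids, c("g1", "g2", "g3", "g4", "g5"))
  expect_identical(out$counts$obs_ids, c("c1", "c2", "c3", "c4"))
  expect_equal(out$report$genes_removed_low_detection, 1)
  expect_equal(out$report$cells_removed_mito, 1)
  expect_equal(out$report$cells_removed_min_genes, 0)
  expect_equal(out$report$n_cells_out, 4)
})

test_that("vacuous thresholds leave the matrix untouched; all-zero dies", {
  x <- toy_qc_matrix()
  thr <- qc_thresholds(min_cells_per_gene = -1, min_genes_per_cell = -1,
                       gene_count_range = c(0, Inf), max_mito_percent = 100)
  out <- apply_qc(x, thr, mito_genes = "g5")
  expect_equal(out$counts$values, x$values)

  z <- em(matrix(0, 4, 3), mode = "raw_counts")
  res <- suppressWarnings(apply_qc(z, qc_thresholds()))
  expect_equal(dim(res$counts$values), c(0L, 0L))
  expect_warning(apply_qc(z, qc_thresholds()), "every cell")
})

test_that("QC is idempotent and preserves label order", {
  set.seed(4)
  x <- em(matrix(rpois(300 * 80, 1.5), 300, 80), mode = "raw_counts")
  thr <- qc_thresholds(min_cells_per_gene = 3, min_genes_per_cell = 100,
                       gene_count_range = c(50, 290), max_mito_percent = 100)
  once <- apply_qc(x, thr)
  twice <- apply_qc(once$counts, thr)
  expect_equal(twice$counts$values, once$counts$values)
  expect_identical(once$counts$obs_ids,
                   x$obs_ids[x$obs_ids %in% once$counts$obs_ids])
  expect_identical(once$counts$gene_ids,
                   x$gene_ids[x$gene_ids %in% once$counts$gene_ids])
})

test_that("lognormalize scales to the target library and is scale-invariant", {
  x <- em(matrix(c(1, 0, 3), ncol = 1), mode = "raw_counts")
  n <- lognormalize(x, scale_factor = 4)
  expect_equal(unname(n$values[, 1]), c(log1p(1), 0, log1p(3)))

  y <- em(cbind(c(2, 1, 5), c(4, 2, 10)), mode = "raw_counts")
  ny <- lognormalize(y)
  expect_equal(unname(ny$values[, 1]), unname(ny$values[, 2]))

  set.seed(7)
  z <- em(matrix(rpois(50 * 10, 3) + 1, 50, 10), mode = "raw_counts")
  nz <- lognormalize(z, scale_factor = 1e4)
  expect_equal(unname(colSums(expm1(nz$values))), rep(1e4, 10))

  # monotone within each cell
  ordz <- apply(z$values, 2, order)
  ordn <- apply(nz$values, 2, order)
  expect_equal(ordn, ordz)

  zero <- em(cbind(c(1, 2), c(0, 0)), mode = "raw_counts")
  expect_error(lognormalize(zero), "QC")
})

test_that("median-of-ratios factors behave under symmetry and scaling", {
  a <- c(10, 20, 5, 40)
  x <- em(cbind(a, a), mode = "raw_counts")
  n <- normalize_bulk(x)
  expect_equal(unname(attr(n, "size_factors")), c(1, 1))
  expect_equal(n$values[, 1], n$values[, 2], ignore_attr = TRUE)

  y <- em(cbind(a, 2 * a), mode = "raw_counts")
  ny <- normalize_bulk(y)
  sf <- attr(ny, "size_factors")
  expect_equal(unname(sf[2] / sf[1]), 2)
  expect_equal(ny$values[, 1], ny$values[, 2], ignore_attr = TRUE)
})

test_that("size factors recover simulated library multipliers within 10%", {
  b <- simulate_bulk_cohort(sim_bulk_spec(n_samples = 10, n_genes = 200,
                                          program_coupling = 0,
                                          immune_couplings = c(s1 = 0),
                                          seed = 13))
  n <- normalize_bulk(b$counts)
  sf <- attr(n, "size_factors")
  rel <- (sf / exp(mean(log(sf)))) /
    (b$lib_factors / exp(mean(log(b$lib_factors))))
  expect_true(all(abs(rel - 1) < 0.1))
})

test_that("size factors agree with the DESeq2 median-of-ratios estimator", {
  set.seed(11)
  m <- matrix(rnbinom(200 * 8, mu = 60, size = 5), 200, 8)
  m <- sweep(m, 2, exp(rnorm(8, 0, 0.4)), "*")
  m <- round(m)
  x <- em(m, mode = "raw_counts")
  sf <- attr(normalize_bulk(x), "size_factors")
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(sf), unname(ref), tolerance = 1e-6)
})

test_that("all-zero-containing gene sets trigger the library-size fallback", {
  m <- rbind(c(5, 0, 3), c(0, 4, 2), c(1, 2, 0))
  x <- em(m, mode = "raw_counts")
  expect_warning(n <- normalize_bulk(x), "library-size")
  expect_equal(unname(attr(n, "size_factors")),
               colSums(m) / exp(mean(log(colSums(m)))))
})
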