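test_that("low-count filter removes a gene only when all samples are below threshold", {
  m <- counts_matrix(matrix(c(5, 9, 3,
                              5, 12, 3,
                              10, 10, 10), nrow = 3, byrow = TRUE,
                            dimnames = list(c("gA", "gB", "gC"),
                                            c("DN3_1", "DN3_2", "CD4SP_1"))))
  kept <- filter_low_counts(m, min_count = 10)
  expect_setequal(rownames(kept$counts), c("gB", "gC"))
  expect_error(filter_low_counts(m, min_count = -1), "min_count")
})

test_that("median-of-ratios size factors match hand-computed values", {
  # identical columns -> unit factors
  m <- counts_matrix(matrix(c(10, 10, 30, 30), nrow = 2, byrow = TRUE,
                            dimnames = list(c("g1", "g2"), c("A_1", "A_2"))))
  expect_equal(size_factors(m), c(A_1 = 1, A_2 = 1))
  # 2x2 worked example: rows (10,20),(30,60) -> (1/sqrt(2), sqrt(2))
  m2 <- counts_matrix(matrix(c(10, 20, 30, 60), nrow = 2, byrow = TRUE,
                             dimnames = list(c("g1", "g2"), c("A_1", "B_1"))))
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)
  # all-zero gene everywhere -> error
  m3 <- counts_matrix(matrix(0L, 2, 2,
                             dimnames = list(c("g1", "g2"), c("A_1", "A_2"))))
  expect_error(size_factors(m3), "size factors")
})

test_that("size factors have the column-scaling property and ignore gene order", {
  set.seed(5)
  counts <- matrix(rnbinom(200, mu = 100, size = 5) + 1L, nrow = 50,
                   dimnames = list(sprintf("g%02d", 1:50),
                                   c("A_1", "A_2", "B_1", "B_2")))
  m <- counts_matrix(counts)
  f <- size_factors(m)
  scaled <- counts
  scaled[, 2] <- scaled[, 2] * 3L
  f2 <- size_factors(counts_matrix(scaled))
  # scaling a column by c multiplies its factor relative to every other
  # column by exactly c (absolute factors shift together by c^(-1/m),
  # since each gene's geometric mean absorbs c^(1/m))
  expect_equal(f2[2] / f2[-2], 3 * f[2] / f[-2], tolerance = 1e-12)
  expect_equal(f2[-2] / f2[1], f[-2] / f[1], tolerance = 1e-12)
  shuffled <- counts[sample.int(50), ]
  expect_equal(size_factors(counts_matrix(shuffled)), f, tolerance = 1e-12)
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(9)
  counts <- matrix(rnbinom(400, mu = 50, size = 2) + 1L, nrow = 100,
                   dimnames = list(sprintf("g%03d", 1:100),
                                   c("A_1", "A_2", "B_1", "B_2")))
  ours <- unname(size_factors(counts_matrix(counts)))
  ref <- unname(DESeq2::estimateSizeFactorsForMatrix(counts))
  expect_equal(ours, ref, tolerance = 1e-8)
})

test_that("normalization divides by factors and preserves column-sum identity", {
  counts <- matrix(c(30L, 60L, 15L, 45L), nrow = 2,
                   dimnames = list(c("g1", "g2"), c("A_1", "B_1")))
  m <- counts_matrix(counts)
  norm <- normalize_counts(m, c(1.5, 1))
  expect_equal(norm$counts["g1", "A_1"], 20)
  expect_true(norm$normalized)
  expect_equal(colSums(norm$counts), colSums(counts) / c(A_1 = 1.5, B_1 = 1))
  expect_equal(normalize_counts(m, c(1, 1))$counts, counts + 0)
  expect_error(normalize_counts(m, c(0, 1)), "positive")
})

test_that("stage log2 fold changes use stage means with a pseudocount", {
  counts <- matrix(c(4, 4, 16, 16,
                     8, 8, 8, 8), nrow = 2, byrow = TRUE,
                   dimnames = list(c("up", "flat"),
                                   c("DN3_1", "DN3_2", "CD4SP_1", "CD4SP_2")))
  m <- counts_matrix(counts, normalized = TRUE)
  cmp0 <- stage_log2fc(m, "DN3", "CD4SP", pseudocount = 0)
  expect_equal(cmp0$table$log2fc, c(2, 0))
  cmp1 <- stage_log2fc(m, "DN3", "CD4SP", pseudocount = 1)
  expect_equal(cmp1$table$log2fc[1], log2(17 / 5), tolerance = 1e-12)
  expect_error(stage_log2fc(m, "DN3", "Th17"), "unknown stage")
  expect_error(stage_log2fc(counts_matrix(counts), "DN3", "CD4SP"), "normalized")
})

test_that("fold-change gates are strict and upregulated is a subset of changed", {
  tab <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                    base_mean = 1, target_mean = 1,
                    log2fc = c(1.0, 1.0001, -1.5, 0.5, -1.0))
  cmp <- structure(list(table = tab, base = "DN3", target = "CD4SP",
                        pseudocount = 1), class = "stage_comparison")
  expect_setequal(changed_genes(cmp), c("b", "c"))       # exactly 1.0 excluded
  expect_setequal(upregulated_genes(cmp), "b")
  set.seed(3)
  for (i in 1:20) {
    tab$log2fc <- rnorm(5, sd = 2)
    cmp$table <- tab
    expect_true(all(upregulated_genes(cmp) %in% changed_genes(cmp)))
  }
})
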