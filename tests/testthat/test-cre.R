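ps <- function(df, assay, state = "DP") peak_set(df, assay, state)

test_that("CRE candidates are ATAC peaks with qualifying H3K27Ac overlap", {
  atac <- ps(genomic_intervals(c("chr1", "chr1"), c(100L, 1000L), c(300L, 1100L)),
             "ATAC")
  k27 <- ps(genomic_intervals("chr1", 250L, 400L), "H3K27Ac")
  out <- cre_candidates(atac, k27)
  expect_equal(nrow(out$intervals), 1L)
  expect_equal(out$intervals$start, 100L)   # ATAC coordinates retained
  expect_equal(out$assay, "ATAC")

  # half-open adjacency does not qualify
  atac2 <- ps(genomic_intervals("chr1", 100L, 200L), "ATAC")
  k27b <- ps(genomic_intervals("chr1", 200L, 300L), "H3K27Ac")
  expect_equal(nrow(cre_candidates(atac2, k27b)$intervals), 0L)

  expect_error(cre_candidates(k27, k27), "ATAC")
  expect_error(cre_candidates(atac, ps(genomic_intervals("chr1", 1L, 2L),
                                       "H3K27Ac", "Th0")), "states differ")
})

test_that("CRE candidates equal the brute-force all-pairs filter", {
  set.seed(77)
  for (rep in 1:5) {
    a <- random_intervals(60)
    k <- random_intervals(40)
    got <- cre_candidates(ps(a, "ATAC"), ps(k, "H3K27Ac"), min_bp = 10)$intervals
    want_rows <- vapply(seq_len(nrow(a)), function(i) {
      nrow(brute_force_query(k, as.list(a[i, ]), min_bp = 10)) > 0
    }, TRUE)
    want <- a[want_rows, , drop = FALSE]
    rownames(want) <- NULL
    expect_equal(got, want)
    expect_true(all(paste(got$chrom, got$start) %in% paste(a$chrom, a$start)))
  }
})

test_that("peaks inside a gene body link to the overlapped gene", {
  genes <- toy_gene_table()
  link <- assign_peak(iv("chr1", 12000, 12500), genes)
  expect_equal(link$gene_id, "gA")
  expect_equal(link$category, "gene_body")
  expect_equal(link$tss_distance, 2000L)
})

test_that("TSS-proximal peaks link under the strict 10 kb rule with strand-aware side", {
  genes <- toy_gene_table()
  # gA: + strand, tss 10000; edge distance from (500,700) is 10000-699 = 9301
  link <- assign_peak(iv("chr1", 500, 700), genes)
  expect_equal(link$gene_id, "gA")
  expect_equal(link$category, "upstream")
  expect_equal(link$tss_distance, 9301L)
  # (0,100): 10000-99 = 9901 -> linked; (0,5): 9996 -> linked
  expect_equal(assign_peak(iv("chr1", 0, 100), genes)$tss_distance, 9901L)
  expect_equal(assign_peak(iv("chr1", 0, 5), genes)$tss_distance, 9996L)
  # distance exactly 10000 is excluded (strict <)
  expect_null(assign_peak(iv("chr1", 0, 1), toy_gene_table()[1, ]))
  expect_equal(distance_to_point(iv("chr1", 0, 1), 10000L), 10000L)
  # gB: - strand, tss 58000; a peak right of the TSS is upstream for -
  linkb <- assign_peak(iv("chr1", 60000, 60200), genes)
  expect_equal(linkb$gene_id, "gB")
  expect_equal(linkb$category, "upstream")
  # and left of gB body start, between genes: downstream of gB (3' on -)
  linkc <- assign_peak(iv("chr1", 49000, 49100), genes)
  expect_equal(linkc$gene_id, "gB")
  expect_equal(linkc$category, "downstream")
  expect_error(assign_peak(iv("chr1", 0, 1), genes[0, ]), "empty gene")
})

test_that("assignment ties break lexicographically and multi-body peaks pick nearest TSS", {
  genes <- data.frame(gene_id = c("gB", "gA"), chrom = "chr1",
                      start = c(20000L, 20000L), end = c(30000L, 30000L),
                      strand = c("+", "+"), tss = c(20000L, 20000L),
                      stringsAsFactors = FALSE)
  link <- assign_peak(iv("chr1", 21000, 21500), genes)
  expect_equal(link$gene_id, "gA")
  # spanning two bodies: nearest TSS wins
  genes2 <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                       start = c(0L, 900L), end = c(1000L, 2000L),
                       strand = c("+", "+"), tss = c(0L, 900L),
                       stringsAsFactors = FALSE)
  expect_equal(assign_peak(iv("chr1", 950, 980), genes2)$gene_id, "g2")
})

test_that("novel Th0 peaks are those without developmental accessibility", {
  th0 <- ps(genomic_intervals(c("chr1", "chr1"), c(500L, 100L), c(700L, 300L)),
            "ATAC", "Th0")
  dp <- ps(genomic_intervals("chr1", 250L, 400L), "ATAC", "DP")
  sp <- ps(genomic_intervals("chr2", 0L, 100L), "ATAC", "CD4SP")
  novel <- novel_th0_peaks(th0, dp, sp)
  expect_equal(novel$intervals$start, 500L)     # (100,300) overlaps DP by 50
  expect_equal(novel$state, "Th0")
  # post hoc: zero qualifying overlap against developmental sets
  for (i in seq_len(nrow(novel$intervals))) {
    expect_equal(nrow(brute_force_query(rbind(dp$intervals, sp$intervals),
                                        as.list(novel$intervals[i, ]))), 0L)
  }
  # no developmental peaks at all -> everything novel
  none <- ps(genomic_intervals(character(0), integer(0), integer(0)), "ATAC", "DP")
  expect_equal(nrow(novel_th0_peaks(th0, none, none)$intervals), 2L)
})

test_that("novelty filter equals the brute-force complement on random sets", {
  set.seed(123)
  for (rep in 1:5) {
    th0 <- random_intervals(50)
    dp <- random_intervals(30)
    sp <- random_intervals(30)
    got <- novel_th0_peaks(ps(th0, "ATAC", "Th0"), ps(dp, "ATAC", "DP"),
                           ps(sp, "ATAC", "CD4SP"))$intervals
    keep <- vapply(seq_len(nrow(th0)), function(i) {
      nrow(brute_force_query(rbind(dp, sp), as.list(th0[i, ]))) == 0
    }, TRUE)
    want <- th0[keep, , drop = FALSE]
    rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("gene sets from peak assignment are order-invariant", {
  genes <- toy_gene_table()
  peaks <- genomic_intervals(c("chr1", "chr1", "chr1"),
                             c(12000L, 60000L, 500L),
                             c(12500L, 60200L, 700L))
  fwd <- genes_with_novel_peaks(peak_set(peaks, "ATAC", "Th0"), genes)
  rev <- genes_with_novel_peaks(peak_set(peaks[3:1, ], "ATAC", "Th0"), genes)
  expect_identical(fwd, rev)
  expect_setequal(fwd, c("gA", "gB"))
})
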