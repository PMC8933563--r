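# single interval as a plain list
iv <- function(chrom, start, end) list(chrom = chrom, start = start, end = end)

# random interval table on a small toy genome
random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000L,
                             max_len = 500L) {
  start <- sample.int(max_pos, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(max_len, n, replace = TRUE),
             strand = ".", name = NA_character_, score = NA_real_,
             stringsAsFactors = FALSE)
}

# independent brute-force overlap oracle: all-pairs comparison
brute_force_query <- function(df, probe, min_bp = 1L) {
  hit <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    if (df$chrom[i] != probe$chrom) next
    ol <- min(df$end[i], probe$end) - max(df$start[i], probe$start)
    hit[i] <- ol >= min_bp
  }
  df[hit, , drop = FALSE]
}

# brute-force upper-tail hypergeometric via binomial coefficients only
brute_force_hyper <- function(k, K, n, N) {
  upper <- min(K, n)
  if (k > upper) return(0)
  sum(vapply(k:upper, function(x) {
    choose(K, x) * choose(N - K, n - x)
  }, numeric(1))) / choose(N, n)
}

# a 3-stage toy counts matrix written to a temp TSV
write_toy_counts <- function(path, genes = c("gA", "gB", "gC"),
                             counts = rbind(c(5, 9, 3, 100, 110, 120),
                                            c(50, 60, 55, 50, 55, 60),
                                            c(10, 10, 10, 80, 90, 85))) {
  colnames(counts) <- c("DN3_1", "DN3_2", "DN3_3", "CD4SP_1", "CD4SP_2", "CD4SP_3")
  df <- data.frame(gene_id = genes, counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

toy_gene_table <- function() {
  data.frame(gene_id = c("gA", "gB"),
             chrom = c("chr1", "chr1"),
             start = c(10000L, 50000L),
             end = c(20000L, 58000L),
             strand = c("+", "-"),
             tss = c(10000L, 58000L),
             stringsAsFactors = FALSE)
}
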