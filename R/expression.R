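#' Remove genes with uniformly low counts
#'
#' A gene is removed only when every sample's count is strictly below
#' `min_count`; a single sample at or above the threshold keeps the gene.
#'
#' @param m a raw `counts_matrix`
#' @param min_count integer threshold (default 10)
#' @return filtered `counts_matrix`
#' @export
filter_low_counts <- function(m, min_count = 10L) {
  stopifnot(inherits(m, "counts_matrix"))
  if (min_count < 0L) stop("min_count must be >= 0", call. = FALSE)
  if (m$normalized) stop("filter_low_counts expects raw counts", call. = FALSE)
  keep <- apply(m$counts, 1L, function(x) any(x >= min_count))
  counts_matrix(m$counts[keep, , drop = FALSE], stage = m$stage)
}

#' Median-of-ratios size factors
#'
#' For each sample j, the size factor is the median over genes g (restricted
#' to genes with a positive geometric mean across samples) of
#' `count[g, j] / geomean_g`. This is the normalization used for bulk
#' RNA-seq count matrices prior to fold-change computation.
#'
#' @param m a raw `counts_matrix`
#' @return positive numeric vector, one factor per sample
#' @export
size_factors <- function(m) {
  stopifnot(inherits(m, "counts_matrix"))
  counts <- m$counts
  # geometric mean in log space; genes with any zero are excluded (log -Inf)
  loggeo <- rowMeans(log(counts))
  use <- is.finite(loggeo)
  if (!any(use))
    stop("no gene has nonzero counts in every sample; cannot estimate size factors",
         call. = FALSE)
  # median taken in log space: with an even number of genes this averages
  # the two middle log-ratios (geometric mean of the middle ratios), the
  # standard median-of-ratios formulation
  f <- apply(counts[use, , drop = FALSE], 2L, function(col) {
    exp(stats::median(log(col) - loggeo[use]))
  })
  if (any(!is.finite(f) | f <= 0))
    stop("degenerate size factor estimate", call. = FALSE)
  f
}

#' Divide counts by per-sample size factors
#'
#' @param m a `counts_matrix`
#' @param f positive size factors, one per sample (defaults to
#'   [size_factors()] of `m`)
#' @return normalized `counts_matrix`
#' @export
normalize_counts <- function(m, f = size_factors(m)) {
  stopifnot(inherits(m, "counts_matrix"))
  if (length(f) != ncol(m$counts))
    stop("one size factor per sample required", call. = FALSE)
  if (any(f <= 0)) stop("size factors must be positive", call. = FALSE)
  norm <- sweep(m$counts + 0, 2L, f, "/")
  counts_matrix(norm, stage = m$stage, normalized = TRUE)
}

#' Stage-to-stage log2 fold changes
#'
#' Per gene: `log2((mean_target + pc) / (mean_base + pc))` where means are
#' taken over the normalized samples of each stage. The pseudocount keeps
#' the ratio finite for silent genes.
#'
#' @param m a normalized `counts_matrix`
#' @param base,target stage labels present in `m`
#' @param pseudocount added to both stage means (default 1)
#' @return a `stage_comparison`: list with `table` (gene_id, base_mean,
#'   target_mean, log2fc), `base`, `target`, `pseudocount`
#' @export
stage_log2fc <- function(m, base, target, pseudocount = 1) {
  stopifnot(inherits(m, "counts_matrix"))
  if (!m$normalized)
    stop("stage_log2fc expects a normalized counts matrix", call. = FALSE)
  for (st in c(base, target)) {
    if (!st %in% m$stage)
      stop(sprintf("unknown stage label '%s'", st), call. = FALSE)
  }
  base_mean <- rowMeans(m$counts[, m$stage == base, drop = FALSE])
  target_mean <- rowMeans(m$counts[, m$stage == target, drop = FALSE])
  lfc <- log2((target_mean + pseudocount) / (base_mean + pseudocount))
  structure(list(table = data.frame(gene_id = rownames(m$counts),
                                    base_mean = base_mean,
                                    target_mean = target_mean,
                                    log2fc = lfc,
                                    row.names = NULL,
                                    stringsAsFactors = FALSE),
                 base = base, target = target, pseudocount = pseudocount),
            class = "stage_comparison")
}

#' @export
print.stage_comparison <- function(x, ...) {
  cat(sprintf("stage_comparison %s -> %s: %d genes, pseudocount %g\n",
              x$base, x$target, nrow(x$table), x$pseudocount))
  invisible(x)
}

#' Genes changing expression between stages
#'
#' `changed_genes` selects genes with `|log2FC|` strictly above the
#' threshold (fold change > 2 in either direction at the default);
#' `upregulated_genes` requires `log2FC` strictly above it.
#'
#' @param cmp a `stage_comparison` from [stage_log2fc()]
#' @param lfc_threshold positive log2 fold-change threshold (default 1,
#'   i.e. a linear fold change of 2)
#' @return character vector of gene ids
#' @export
changed_genes <- function(cmp, lfc_threshold = 1) {
  stopifnot(inherits(cmp, "stage_comparison"), lfc_threshold > 0)
  cmp$table$gene_id[abs(cmp$table$log2fc) > lfc_threshold]
}

#' @rdname changed_genes
#' @export
upregulated_genes <- function(cmp, lfc_threshold = 1) {
  stopifnot(inherits(cmp, "stage_comparison"), lfc_threshold > 0)
  cmp$table$gene_id[cmp$table$log2fc > lfc_threshold]
}

#' Optional Welch t-test on log-normalized values
#'
#' Two-sided Welch t-test per gene on `log2(normalized + pseudocount)`
#' between two stages. Provided for users who want a p-value column next to
#' the fold-change gate; it is a plain two-sample test, not a count-model
#' Wald test, and is not used by the gating itself.
#'
#' @inheritParams stage_log2fc
#' @return data.frame (gene_id, t, p)
#' @export
stage_welch_test <- function(m, base, target, pseudocount = 1) {
  stopifnot(inherits(m, "counts_matrix"), m$normalized)
  x <- log2(m$counts[, m$stage == base, drop = FALSE] + pseudocount)
  y <- log2(m$counts[, m$stage == target, drop = FALSE] + pseudocount)
  if (ncol(x) < 2L || ncol(y) < 2L)
    stop("Welch test needs >= 2 replicates per stage", call. = FALSE)
  res <- t(vapply(seq_len(nrow(x)), function(i) {
    if (stats::sd(x[i, ]) == 0 && stats::sd(y[i, ]) == 0) {
      if (mean(x[i, ]) == mean(y[i, ])) return(c(0, 1))
      return(c(Inf, 0))
    }
    tt <- stats::t.test(y[i, ], x[i, ])
    c(unname(tt$statistic), tt$p.value)
  }, numeric(2L)))
  data.frame(gene_id = rownames(m$counts), t = res[, 1L], p = res[, 2L],
             row.names = NULL, stringsAsFactors = FALSE)
}
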