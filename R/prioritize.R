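#' Combine criterion gene sets into per-gene signatures
#'
#' One row per universe gene with boolean columns for each criterion and
#' the final `licensed` flag: upregulated AND 5hmC-positive (either state)
#' AND developmental CRE AND stimulus-novel Th0 peak. Every supplied set
#' must be a subset of the universe.
#'
#' @param universe character vector of gene ids (the tested genes, e.g.
#'   those surviving the low-count filter)
#' @param changed,upregulated genes passing the fold-change gates
#' @param hmc_dp,hmc_cd4sp 5hmC-positive genes per state
#' @param dev_cre genes with a developmental CRE
#' @param novel_th0 genes with a stimulus-novel accessible peak
#' @return data.frame of signatures
#' @export
build_signatures <- function(universe, changed, upregulated, hmc_dp, hmc_cd4sp,
                             dev_cre, novel_th0) {
  if (anyDuplicated(universe))
    stop("universe contains duplicate gene ids", call. = FALSE)
  sets <- list(changed = changed, upregulated = upregulated, hmc_dp = hmc_dp,
               hmc_cd4sp = hmc_cd4sp, dev_cre = dev_cre, novel_th0 = novel_th0)
  for (nm in names(sets)) {
    outside <- setdiff(sets[[nm]], universe)
    if (length(outside) > 0L)
      stop(sprintf("set '%s' contains gene(s) outside the universe: %s",
                   nm, outside[1L]), call. = FALSE)
  }
  df <- data.frame(gene_id = universe, stringsAsFactors = FALSE)
  for (nm in names(sets)) df[[nm]] <- universe %in% sets[[nm]]
  df$hmc_any <- df$hmc_dp | df$hmc_cd4sp
  df$licensed <- df$upregulated & df$hmc_any & df$dev_cre & df$novel_th0
  df
}

#' Nested percentage, reported to one decimal
#'
#' `round(100 * child / parent, 1)`; `NA` when the parent count is zero.
#'
#' @param child,parent non-negative counts, child <= parent
#' @return numeric percentage or NA
#' @export
percentage <- function(child, parent) {
  if (parent == 0) return(NA_real_)
  round(100 * child / parent, 1)
}

#' Cascade (Venn) summary of a signature table
#'
#' Counts the nested gene sets of the prioritization cascade — changed,
#' 5hmC-positive among changed, upregulated-and-5hmC (the cascade
#' universe), developmental CRE and stimulus-novel peaks within it, and the
#' final licensed set — with each nested percentage relative to its parent.
#'
#' @param signatures data.frame from [build_signatures()]
#' @return named list of counts and percentages
#' @export
venn_summary <- function(signatures) {
  s <- signatures
  n_changed <- sum(s$changed)
  n_hmc_among_changed <- sum(s$changed & s$hmc_any)
  n_positive_correlation <- sum(s$upregulated & s$hmc_any)
  n_upregulated_hmc <- n_positive_correlation
  n_with_dev_cre <- sum(s$upregulated & s$hmc_any & s$dev_cre)
  n_with_novel_th0 <- sum(s$upregulated & s$hmc_any & s$novel_th0)
  n_licensed <- sum(s$licensed)
  list(n_universe = nrow(s),
       n_changed = n_changed,
       n_hmc_among_changed = n_hmc_among_changed,
       n_positive_correlation = n_positive_correlation,
       n_upregulated_hmc = n_upregulated_hmc,
       n_with_dev_cre = n_with_dev_cre,
       n_with_novel_th0 = n_with_novel_th0,
       n_licensed = n_licensed,
       pct_hmc_among_changed = percentage(n_hmc_among_changed, n_changed),
       pct_positive_correlation = percentage(n_positive_correlation,
                                             n_hmc_among_changed),
       pct_with_dev_cre = percentage(n_with_dev_cre, n_upregulated_hmc),
       pct_with_novel_th0 = percentage(n_with_novel_th0, n_upregulated_hmc),
       pct_licensed = percentage(n_licensed, n_upregulated_hmc))
}

#' Upper-tail hypergeometric p-value
#'
#' P(X >= k) for X ~ Hypergeometric drawing `n` genes from a universe of
#' `N` that contains `K` term genes.
#'
#' @param k observed overlap
#' @param K term size in the universe
#' @param n query-set size
#' @param N universe size
#' @return p-value in \[0, 1\]
#' @export
hypergeom_p <- function(k, K, n, N) {
  if (k < 0 || K < 0 || n < 0 || N < 1 || K > N || n > N || k > min(K, n))
    stop("inconsistent hypergeometric counts", call. = FALSE)
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted values
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} (m * p_(j) / j)` capped at
#' 1, returned in the input order.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\]
#' @return adjusted values, same length and order
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0L))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' Hypergeometric gene-set enrichment with BH correction
#'
#' Tests each annotation term against the query set over the given
#' universe. Term gene lists are intersected with the universe before
#' testing; terms with zero overlap with the query are dropped before the
#' BH correction (so `m` counts only reported terms). Results are sorted by
#' p-value, ties broken by term id for determinism.
#'
#' @param query character vector of gene ids, subset of `universe`
#' @param terms named list mapping term ids to gene-id vectors (see
#'   [read_term_map()])
#' @param universe character vector of gene ids
#' @return data.frame (term_id, k, K, n, N, p, q) sorted by p
#' @export
enrich <- function(query, terms, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  outside <- setdiff(query, universe)
  if (length(outside) > 0L)
    stop(sprintf("query gene outside universe: %s", outside[1L]), call. = FALSE)
  query <- unique(query)
  n <- length(query)
  N <- length(universe)
  rows <- lapply(sort(names(terms)), function(tid) {
    tg <- intersect(unique(terms[[tid]]), universe)
    k <- length(intersect(tg, query))
    if (k == 0L) return(NULL)
    data.frame(term_id = tid, k = k, K = length(tg), n = n, N = N,
               p = hypergeom_p(k, length(tg), n, N),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) {
    return(data.frame(term_id = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      q = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Recovery report against planted truth
#'
#' Compares pipeline signatures with the planted class labels of a
#' synthetic bundle. Sensitivity is the fraction of truth-licensed genes
#' flagged licensed (`NA` when none were planted); each partial class
#' reports its leakage — the fraction of its genes wrongly flagged
#' licensed.
#'
#' @param truth data.frame (gene_id, class) from the synthetic generator
#' @param signatures data.frame from [build_signatures()]
#' @return list with `sensitivity` and named `leakage` vector
#' @export
recovery_report <- function(truth, signatures) {
  if (!setequal(truth$gene_id, signatures$gene_id))
    stop("truth and signatures cover different gene universes", call. = FALSE)
  flagged <- stats::setNames(signatures$licensed, signatures$gene_id)
  lic <- truth$gene_id[truth$class == "licensed"]
  sensitivity <- if (length(lic) == 0L) NA_real_ else mean(flagged[lic])
  partial <- setdiff(unique(truth$class), c("licensed", "null"))
  leakage <- vapply(partial, function(cl) {
    g <- truth$gene_id[truth$class == cl]
    mean(flagged[g])
  }, numeric(1L))
  null_genes <- truth$gene_id[truth$class == "null"]
  if (length(null_genes) > 0L)
    leakage <- c(leakage, null = mean(flagged[null_genes]))
  list(sensitivity = sensitivity, leakage = leakage)
}
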