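#' Gene-body 5hmC enrichment score
#'
#' Aggregates CMS-IP and input coverage over a gene body as
#' coverage-weighted sums (segment value x bp of overlap with the body) and
#' scores the gene as `log2((S_ip + pc) / (S_input + pc))`. Only intragenic
#' signal counts: segments are clipped to the gene body and promoter flanks
#' are excluded, since 5hmC is depleted at transcription start sites and the
#' criterion of interest is intragenic enrichment.
#'
#' @param ip,input `signal_track` objects (see [read_bedgraph()])
#' @param gene one row of a gene table (list or one-row data.frame with
#'   chrom, start, end, gene_id)
#' @param pseudocount added to both sums (default 1)
#' @param mode `"sum"` (default, coverage-weighted sum) or `"mean"`
#'   (per-bp mean signal over the body)
#' @return numeric log2 ratio
#' @export
gene_hmc_score <- function(ip, input, gene, pseudocount = 1, mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  if (gene$end <= gene$start) stop("zero-length gene body", call. = FALSE)
  s_ip <- track_body_sum(ip, gene)
  s_in <- track_body_sum(input, gene)
  if (mode == "mean") {
    len <- gene$end - gene$start
    s_ip <- s_ip / len
    s_in <- s_in / len
  }
  log2((s_ip + pseudocount) / (s_in + pseudocount))
}

track_body_sum <- function(track, gene) {
  seg <- track[track$chrom == gene$chrom &
                 track$end > gene$start & track$start < gene$end, , drop = FALSE]
  if (nrow(seg) == 0L) return(0)
  ol <- pmin(seg$end, gene$end) - pmax(seg$start, gene$start)
  sum(seg$value * ol)
}

#' Score all genes of a table against one state's IP/input tracks
#'
#' @param ip,input `signal_track` objects for one cell state
#' @param genes gene table (see [read_gene_table()])
#' @param state cell-state label recorded in the output
#' @inheritParams gene_hmc_score
#' @return data.frame (gene_id, state, log2_ratio)
#' @export
hmc_scores <- function(ip, input, genes, state, pseudocount = 1,
                       mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  scores <- vapply(seq_len(nrow(genes)), function(i) {
    gene_hmc_score(ip, input, genes[i, ], pseudocount = pseudocount, mode = mode)
  }, numeric(1L))
  data.frame(gene_id = genes$gene_id, state = state, log2_ratio = scores,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' 5hmC-positive gene sets per state and their union
#'
#' A gene is positive in a state when its log2 IP/input ratio is strictly
#' above `threshold`. The union set contains genes positive in at least one
#' state.
#'
#' @param scores data.frame as returned by [hmc_scores()], possibly
#'   row-bound across states
#' @param threshold log2-ratio cutoff, strict (default 2)
#' @return list with one gene-id vector per state plus `union`
#' @export
hmc_positive_genes <- function(scores, threshold = 2) {
  stopifnot(all(c("gene_id", "state", "log2_ratio") %in% names(scores)))
  pos <- scores[scores$log2_ratio > threshold, , drop = FALSE]
  per_state <- lapply(split(pos$gene_id, factor(pos$state, levels = unique(scores$state))),
                      unique)
  c(per_state, list(union = unique(pos$gene_id)))
}

#' Positive genes with higher 5hmC in the precursor state
#'
#' Among genes 5hmC-positive in either state, returns those whose DP score
#' strictly exceeds the CD4SP score (demethylation initiated early in
#' commitment). Both inputs must score the same genes.
#'
#' @param scores_dp,scores_cd4sp per-state score data.frames from
#'   [hmc_scores()]
#' @param threshold positivity cutoff applied to either state (strict)
#' @return character vector of gene ids
#' @export
hmc_higher_in_dp <- function(scores_dp, scores_cd4sp, threshold = 2) {
  if (!setequal(scores_dp$gene_id, scores_cd4sp$gene_id) ||
      anyDuplicated(scores_dp$gene_id) || anyDuplicated(scores_cd4sp$gene_id))
    stop("both states must score the same genes exactly once", call. = FALSE)
  dp <- stats::setNames(scores_dp$log2_ratio, scores_dp$gene_id)
  sp <- scores_cd4sp$log2_ratio
  names(sp) <- scores_cd4sp$gene_id
  sp <- sp[names(dp)]
  positive <- names(dp)[dp > threshold | sp > threshold]
  positive[dp[positive] > sp[positive]]
}
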