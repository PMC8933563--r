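#' Developmental CRE candidates: ATAC peaks with H3K27Ac support
#'
#' Returns the subset of ATAC peaks that overlap at least one H3K27Ac peak
#' by `min_bp` or more, for a single cell state. The ATAC peak is the
#' positional anchor; H3K27Ac serves only as activity evidence, so ATAC
#' coordinates are retained unchanged.
#'
#' @param atac ATAC [peak_set()]
#' @param k27ac H3K27Ac [peak_set()] for the same cell state
#' @param min_bp minimum overlap in bp (default 1)
#' @return a `peak_set` (assay ATAC, state taken from `atac`)
#' @export
cre_candidates <- function(atac, k27ac, min_bp = 1L) {
  stopifnot(inherits(atac, "peak_set"), inherits(k27ac, "peak_set"))
  if (atac$assay != "ATAC")
    stop(sprintf("first argument must be an ATAC peak set (got %s)", atac$assay),
         call. = FALSE)
  if (k27ac$assay != "H3K27Ac")
    stop(sprintf("second argument must be an H3K27Ac peak set (got %s)", k27ac$assay),
         call. = FALSE)
  if (atac$state != k27ac$state)
    stop(sprintf("cell states differ: %s vs %s", atac$state, k27ac$state),
         call. = FALSE)
  keep <- peaks_with_overlap(atac$intervals, k27ac$intervals, min_bp)
  out <- atac$intervals[keep, , drop = FALSE]
  rownames(out) <- NULL
  peak_set(out, assay = "ATAC", state = atac$state)
}

# logical vector: which rows of `query` overlap any row of `subject` by >= min_bp
peaks_with_overlap <- function(query, subject, min_bp = 1L) {
  if (min_bp < 1L) stop("min_bp must be >= 1", call. = FALSE)
  if (nrow(query) == 0L) return(logical(0L))
  if (nrow(subject) == 0L) return(rep(FALSE, nrow(query)))
  hits <- GenomicRanges::findOverlaps(intervals_to_granges(query),
                                      intervals_to_granges(subject),
                                      minoverlap = as.integer(min_bp))
  seq_len(nrow(query)) %in% S4Vectors::queryHits(hits)
}

#' Assign a peak to a gene
#'
#' If the peak overlaps one or more gene bodies, it is linked to the
#' overlapped gene with the nearest TSS (category `gene_body`). Otherwise
#' it is linked to the gene with the minimum TSS distance provided that
#' distance is strictly below `max_tss_dist`; the category is `upstream`
#' or `downstream` of the TSS relative to the gene's strand. Ties in TSS
#' distance are broken by lexicographically smallest `gene_id`. Distances
#' are measured from the nearest peak edge (`anchor = "edge"`) or from the
#' peak midpoint (`anchor = "midpoint"`).
#'
#' @param peak single interval (list or one-row data frame)
#' @param genes gene table (see [read_gene_table()])
#' @param max_tss_dist maximum TSS distance in bp, strict (default 10000)
#' @param anchor distance anchor, `"edge"` (default) or `"midpoint"`
#' @param gene_index optional prebuilt [build_index()] over the gene bodies
#'   (rows must correspond to `genes`)
#' @return a one-row data.frame (chrom, start, end, gene_id, category,
#'   tss_distance) or `NULL` when no gene qualifies
#' @export
assign_peak <- function(peak, genes, max_tss_dist = 10000L,
                        anchor = c("edge", "midpoint"), gene_index = NULL) {
  anchor <- match.arg(anchor)
  if (nrow(genes) == 0L) stop("empty gene table", call. = FALSE)
  probe <- peak_anchor(peak, anchor)
  same_chrom <- genes$chrom == peak$chrom
  body_ol <- overlap_length_vec(genes, peak)
  hit <- which(body_ol >= 1L)
  if (length(hit) > 0L) {
    d <- vapply(hit, function(i) distance_to_point(probe, genes$tss[i]), 0L)
    pick <- hit[order(d, genes$gene_id[hit])][1L]
    return(peak_gene_link(peak, genes[pick, ], "gene_body",
                          distance_to_point(probe, genes$tss[pick])))
  }
  cand <- which(same_chrom)
  if (length(cand) == 0L) return(NULL)
  d <- vapply(cand, function(i) distance_to_point(probe, genes$tss[i]), 0L)
  ord <- order(d, genes$gene_id[cand])
  best <- cand[ord[1L]]
  best_d <- d[ord[1L]]
  if (best_d >= max_tss_dist) return(NULL)
  gene <- genes[best, ]
  # which side of the TSS the peak lies on; a peak straddling the TSS
  # without touching the body is treated as promoter-proximal (upstream)
  side <- if (gene$tss >= peak$end) "left"
          else if (gene$tss < peak$start) "right"
          else "straddle"
  category <- if (side == "straddle") "upstream"
              else if ((side == "left" && gene$strand == "+") ||
                       (side == "right" && gene$strand == "-")) "upstream"
              else "downstream"
  peak_gene_link(peak, gene, category, best_d)
}

peak_anchor <- function(peak, anchor) {
  if (anchor == "edge") return(peak)
  mid <- as.integer((peak$start + peak$end) %/% 2L)
  list(chrom = peak$chrom, start = mid, end = mid + 1L)
}

peak_gene_link <- function(peak, gene, category, tss_distance) {
  data.frame(chrom = peak$chrom, start = peak$start, end = peak$end,
             gene_id = gene$gene_id, category = category,
             tss_distance = as.integer(tss_distance),
             stringsAsFactors = FALSE)
}

#' Assign every peak of a set to genes
#'
#' @param peaks a [peak_set()]
#' @inheritParams assign_peak
#' @return data.frame of links (possibly zero rows), one per assignable peak
#' @export
assign_peaks <- function(peaks, genes, max_tss_dist = 10000L,
                         anchor = c("edge", "midpoint")) {
  anchor <- match.arg(anchor)
  df <- peaks$intervals
  links <- lapply(seq_len(nrow(df)), function(i) {
    assign_peak(df[i, ], genes, max_tss_dist = max_tss_dist, anchor = anchor)
  })
  links <- links[!vapply(links, is.null, TRUE)]
  if (length(links) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      gene_id = character(0), category = character(0),
                      tss_distance = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, links)
  rownames(out) <- NULL
  out
}

#' Genes carrying a developmental CRE in either precursor state
#'
#' Assigns each CRE candidate peak (output of [cre_candidates()]) from both
#' developmental states to genes and returns every gene receiving at least
#' one link.
#'
#' @param cre_dp,cre_cd4sp CRE-candidate [peak_set()]s for the two states
#' @param genes gene table
#' @inheritParams assign_peak
#' @return character vector of gene ids (sorted, unique)
#' @export
genes_with_dev_cre <- function(cre_dp, cre_cd4sp, genes, max_tss_dist = 10000L) {
  links <- rbind(assign_peaks(cre_dp, genes, max_tss_dist),
                 assign_peaks(cre_cd4sp, genes, max_tss_dist))
  sort(unique(links$gene_id))
}

#' Stimulus-novel accessible peaks
#'
#' Th0 (activated) ATAC peaks with no qualifying overlap (>= `min_bp`, or
#' reciprocal fraction >= `min_frac` when given) against any developmental
#' ATAC peak in DP or CD4SP — sites that only become accessible upon
#' stimulation.
#'
#' @param th0_atac,dp_atac,cd4sp_atac ATAC [peak_set()]s
#' @param min_bp overlap (bp) at or above which a Th0 peak is considered
#'   developmentally accessible (default 1)
#' @param min_frac optional reciprocal-overlap fraction in (0, 1]; when
#'   given, a Th0 peak is disqualified only if some developmental peak
#'   overlaps it by at least this fraction of both peak lengths
#' @return a `peak_set` (assay ATAC, state Th0) of novel peaks
#' @export
novel_th0_peaks <- function(th0_atac, dp_atac, cd4sp_atac, min_bp = 1L,
                            min_frac = NULL) {
  for (ps in list(th0_atac, dp_atac, cd4sp_atac)) {
    stopifnot(inherits(ps, "peak_set"))
    if (ps$assay != "ATAC")
      stop("novel_th0_peaks expects ATAC peak sets", call. = FALSE)
  }
  dev <- rbind(dp_atac$intervals, cd4sp_atac$intervals)
  q <- th0_atac$intervals
  if (nrow(q) == 0L || nrow(dev) == 0L) {
    out <- q
  } else if (is.null(min_frac)) {
    out <- q[!peaks_with_overlap(q, dev, min_bp), , drop = FALSE]
  } else {
    disqualified <- vapply(seq_len(nrow(q)), function(i) {
      ol <- overlap_length_vec(dev, q[i, ])
      any(ol / (q$end[i] - q$start[i]) >= min_frac &
            ol / (dev$end - dev$start) >= min_frac)
    }, TRUE)
    out <- q[!disqualified, , drop = FALSE]
  }
  rownames(out) <- NULL
  peak_set(out, assay = "ATAC", state = th0_atac$state)
}

#' Genes near stimulus-novel peaks
#'
#' Applies [assign_peak()] (gene body or < `max_tss_dist` from the nearest
#' TSS) to each novel peak and returns the genes receiving links.
#'
#' @param novel novel-peak set from [novel_th0_peaks()]
#' @param genes gene table
#' @inheritParams assign_peak
#' @return character vector of gene ids (sorted, unique)
#' @export
genes_with_novel_peaks <- function(novel, genes, max_tss_dist = 10000L) {
  sort(unique(assign_peaks(novel, genes, max_tss_dist)$gene_id))
}
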