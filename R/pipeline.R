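#' Default pipeline thresholds
#'
#' The gates of the prioritization cascade: genes kept when any sample has
#' `min_count` reads or more; fold-change gate strictly above
#' `lfc_threshold` on the log2 scale (fold change > 2); 5hmC gate strictly
#' above `hmc_threshold` (log2 IP/input > 2); peak-to-gene assignment
#' inside the gene body or strictly below `max_tss_dist` from the nearest
#' TSS; peak overlaps qualify at `min_overlap_bp` or more.
#'
#' @return named list of thresholds
#' @export
default_thresholds <- function() {
  list(min_count = 10L, lfc_threshold = 1, hmc_threshold = 2,
       max_tss_dist = 10000L, min_overlap_bp = 1L)
}

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop(sprintf("config file not found: %s", config), call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  thr <- utils::modifyList(default_thresholds(), config$thresholds %||% list())
  if (any(unlist(thr) <= 0)) stop("thresholds must be positive", call. = FALSE)
  config$thresholds <- thr
  config$pseudocount <- utils::modifyList(list(expression = 1, hmc = 1),
                                          config$pseudocount %||% list())
  config$stages <- utils::modifyList(list(base = "DN3", target = "CD4SP",
                                          activated = "Th0"),
                                     config$stages %||% list())
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full prioritization pipeline
#'
#' Reads every input named in the config, applies the cascade — count
#' filtering, median-of-ratios normalization, fold-change gating, gene-body
#' 5hmC scoring, developmental CRE detection, stimulus-novel peak calling
#' and peak-to-gene assignment — and writes the per-gene signature table,
#' the cascade summary (JSON), the novel-peak BED, an optional enrichment
#' table, and a run log. Identical config and inputs produce byte-identical
#' outputs.
#'
#' @param config path to a YAML config (as written by
#'   [generate_synthetic_bundle()]) or an equivalent nested list; see the
#'   package vignette for the schema
#' @param out_dir output directory (created if needed)
#' @return invisibly, a list with `signatures`, `venn`, `novel_peaks`,
#'   `enrichment` (or NULL) and output `paths`
#' @export
run_pipeline <- function(config, out_dir) {
  config <- read_pipeline_config(config)
  thr <- config$thresholds
  inp <- config$inputs
  if (is.null(inp)) stop("config lacks an 'inputs' section", call. = FALSE)

  flat <- unlist(inp[c("gene_table", "counts", "hmc", "atac", "k27ac")])
  missing <- flat[!file.exists(flat)]
  if (length(missing) > 0L)
    stop(sprintf("input file not found: %s", missing[1L]), call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  stage_fail <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  genes <- stage_fail("gene_table", read_gene_table(inp$gene_table))

  ## expression gating
  expr <- stage_fail("expression", {
    m <- read_counts(inp$counts)
    m <- filter_low_counts(m, thr$min_count)
    norm <- normalize_counts(m, size_factors(m))
    cmp <- stage_log2fc(norm, config$stages$base, config$stages$target,
                        pseudocount = config$pseudocount$expression)
    list(cmp = cmp,
         changed = changed_genes(cmp, thr$lfc_threshold),
         upregulated = upregulated_genes(cmp, thr$lfc_threshold))
  })
  universe <- intersect(genes$gene_id, expr$cmp$table$gene_id)
  genes_u <- genes[genes$gene_id %in% universe, , drop = FALSE]

  ## 5hmC gene-body enrichment per developmental state
  hmc <- stage_fail("hmc", {
    per_state <- lapply(names(inp$hmc), function(state) {
      hmc_scores(read_bedgraph(inp$hmc[[state]]$ip),
                 read_bedgraph(inp$hmc[[state]]$input),
                 genes_u, state = state,
                 pseudocount = config$pseudocount$hmc)
    })
    names(per_state) <- names(inp$hmc)
    pos <- hmc_positive_genes(do.call(rbind, per_state), thr$hmc_threshold)
    list(scores = per_state, pos = pos)
  })

  ## developmental CREs: ATAC with H3K27Ac support, per state, then
  ## assignment to genes
  dev_cre <- stage_fail("cre_annotation", {
    cre_sets <- lapply(names(inp$k27ac), function(state) {
      cre_candidates(read_bed(inp$atac[[state]], "ATAC", state),
                     read_bed(inp$k27ac[[state]], "H3K27Ac", state),
                     min_bp = thr$min_overlap_bp)
    })
    do.call(genes_with_dev_cre,
            c(cre_sets[1:2], list(genes = genes_u,
                                  max_tss_dist = thr$max_tss_dist)))
  })

  ## stimulus-novel accessibility
  novel <- stage_fail("novel_peaks", {
    dev_states <- setdiff(names(inp$atac), config$stages$activated)
    np <- novel_th0_peaks(
      read_bed(inp$atac[[config$stages$activated]], "ATAC",
               config$stages$activated),
      read_bed(inp$atac[[dev_states[1L]]], "ATAC", dev_states[1L]),
      read_bed(inp$atac[[dev_states[2L]]], "ATAC", dev_states[2L]),
      min_bp = thr$min_overlap_bp)
    list(peaks = np,
         genes = genes_with_novel_peaks(np, genes_u, thr$max_tss_dist))
  })

  ## integration
  signatures <- stage_fail("prioritization", build_signatures(
    universe = universe,
    changed = intersect(expr$changed, universe),
    upregulated = intersect(expr$upregulated, universe),
    hmc_dp = intersect(hmc$pos$DP %||% character(0), universe),
    hmc_cd4sp = intersect(hmc$pos$CD4SP %||% character(0), universe),
    dev_cre = intersect(dev_cre, universe),
    novel_th0 = intersect(novel$genes, universe)))
  venn <- venn_summary(signatures)

  enrichment <- NULL
  if (!is.null(inp$term_map)) {
    enrichment <- stage_fail("enrichment", enrich(
      query = signatures$gene_id[signatures$licensed],
      terms = read_term_map(inp$term_map),
      universe = universe))
  }

  ## outputs
  paths <- list(signatures = file.path(out_dir, "signatures.tsv"),
                venn = file.path(out_dir, "venn.json"),
                novel_peaks = file.path(out_dir, "novel_peaks.bed"),
                comparison = file.path(out_dir, "stage_comparison.tsv"),
                log = file.path(out_dir, "run_log.txt"))
  utils::write.table(signatures, paths$signatures, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(venn, paths$venn, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  write_bed(novel$peaks, paths$novel_peaks)
  cmp_tab <- expr$cmp$table
  cmp_tab$log2fc <- round(cmp_tab$log2fc, 6)
  cmp_tab$base_mean <- round(cmp_tab$base_mean, 6)
  cmp_tab$target_mean <- round(cmp_tab$target_mean, 6)
  utils::write.table(cmp_tab, paths$comparison, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(enrichment)) {
    paths$enrichment <- file.path(out_dir, "enrichment.tsv")
    etab <- enrichment
    etab$p <- signif(etab$p, 10)
    etab$q <- signif(etab$q, 10)
    utils::write.table(etab, paths$enrichment, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  writeLines(c(sprintf("config_md5\t%s", config_hash(config)),
               sprintf("%s\t%s", names(venn),
                       vapply(venn, function(v)
                         if (is.na(v)) "NA" else format_num(v), ""))),
             paths$log)

  invisible(list(signatures = signatures, venn = venn,
                 novel_peaks = novel$peaks, enrichment = enrichment,
                 hmc_scores = hmc$scores, comparison = expr$cmp,
                 paths = paths))
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(utils::capture.output(utils::str(config)), tmp)
  unname(tools::md5sum(tmp))
}
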