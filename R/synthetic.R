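#' Configuration for the synthetic multi-omic bundle
#'
#' Defines a toy genome with planted gene classes and matched RNA-seq
#' counts, 5hmC IP/input tracks and peak sets, so the whole prioritization
#' cascade can run and be validated with no external data. Classes:
#' `licensed` genes satisfy every criterion; each partial class
#' (`no_novel_peak`, `no_dev_cre`, `no_hmc`, `not_upregulated`) omits
#' exactly the named criterion; `null` genes are flat, background-only.
#'
#' @param seed RNG seed; a fixed seed yields byte-identical output files
#' @param n_chromosomes,n_genes genome size
#' @param gene_length_range,intergenic_gap_range bp ranges; the default gap
#'   (25-35 kb) keeps every planted peak unambiguous under the 10 kb
#'   TSS-distance rule
#' @param stages stage labels, base first, target last
#' @param replicates samples per stage
#' @param base_mean,null_mean stage-invariant count means for expressed and
#'   null genes
#' @param lfc planted log2 fold change (base to target) for upregulated
#'   classes
#' @param hmc_factor planted log2 IP/input enrichment for 5hmC-positive
#'   gene bodies (the weaker state is planted 0.5 below this)
#' @param frac_hmc_higher_dp fraction of 5hmC-positive genes planted with
#'   the higher enrichment in DP rather than CD4SP
#' @param background_value per-bp background coverage for both tracks
#' @param bin_width bedGraph bin width in bp
#' @param peak_width,novel_width widths of planted developmental and
#'   Th0-novel peaks (bp)
#' @param novel_offset distance (bp) from the TSS at which Th0-novel peaks
#'   are planted; must stay well below the 10 kb assignment rule so that
#'   bounded jitter cannot flip truth
#' @param fractions named fractions per planted class (licensed,
#'   no_novel_peak, no_dev_cre, no_hmc, not_upregulated); the remainder is
#'   null
#' @param peak_jitter uniform +/- bp shift applied per planted locus (all
#'   peaks of a locus share the shift); 0 disables
#' @param count_noise draw counts from a negative binomial instead of using
#'   the exact class means
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2) when
#'   `count_noise` is on
#' @return a validated `synthetic_config` list
#' @export
synthetic_config <- function(seed = 1L,
                             n_chromosomes = 2L,
                             n_genes = 100L,
                             gene_length_range = c(5000L, 15000L),
                             intergenic_gap_range = c(25000L, 35000L),
                             stages = c("DN3", "DP", "CD4SP"),
                             replicates = 3L,
                             base_mean = 50,
                             null_mean = 30,
                             lfc = 3,
                             hmc_factor = 3,
                             frac_hmc_higher_dp = 0.25,
                             background_value = 2,
                             bin_width = 100L,
                             peak_width = 400L,
                             novel_width = 350L,
                             novel_offset = 3000L,
                             fractions = c(licensed = 0.10, no_novel_peak = 0.05,
                                           no_dev_cre = 0.05, no_hmc = 0.05,
                                           not_upregulated = 0.05),
                             peak_jitter = 0L,
                             count_noise = FALSE,
                             dispersion = 0.05) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              n_genes = as.integer(n_genes),
              gene_length_range = as.integer(gene_length_range),
              intergenic_gap_range = as.integer(intergenic_gap_range),
              stages = stages, replicates = as.integer(replicates),
              base_mean = base_mean, null_mean = null_mean, lfc = lfc,
              hmc_factor = hmc_factor, frac_hmc_higher_dp = frac_hmc_higher_dp,
              background_value = background_value, bin_width = as.integer(bin_width),
              peak_width = as.integer(peak_width), novel_width = as.integer(novel_width),
              novel_offset = as.integer(novel_offset),
              fractions = fractions, peak_jitter = as.integer(peak_jitter),
              count_noise = isTRUE(count_noise), dispersion = dispersion)
  required_classes <- c("licensed", "no_novel_peak", "no_dev_cre", "no_hmc",
                        "not_upregulated")
  if (!all(required_classes %in% names(cfg$fractions)))
    stop("fractions must name every planted class", call. = FALSE)
  if (sum(cfg$fractions) > 1 + 1e-12)
    stop("class fractions must sum to <= 1", call. = FALSE)
  if (any(cfg$fractions < 0)) stop("fractions must be non-negative", call. = FALSE)
  stopifnot(cfg$n_genes >= 1L, cfg$n_chromosomes >= 1L, cfg$replicates >= 1L,
            length(cfg$stages) >= 2L,
            all(cfg$gene_length_range > 0L), all(cfg$intergenic_gap_range > 0L),
            cfg$gene_length_range[2L] >= cfg$gene_length_range[1L],
            cfg$bin_width > 0L, cfg$peak_width > 0L, cfg$novel_width > 0L,
              cfg$base_mean > 0, cfg$null_mean > 0, cfg$lfc > 0, cfg$hmc_factor > 0)
  if (cfg$peak_jitter < 0L) stop("peak_jitter must be >= 0", call. = FALSE)
  # jitter must stay inside the construction slack: half the minimum body
  # minus half the planted peak, and the gap between novel peak and TSS rule
  slack <- min(cfg$gene_length_range[1L] %/% 2L - cfg$peak_width,
               10000L - cfg$novel_offset - cfg$novel_width - 1L)
  if (cfg$peak_jitter > slack)
    stop(sprintf("peak_jitter exceeds construction slack (%d bp)", slack),
         call. = FALSE)
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a synthetic multi-omic bundle with planted truth
#'
#' Writes, under `dir`: the gene table, the stage-labelled counts matrix,
#' 5hmC IP/input bedGraphs for DP and CD4SP, ATAC BED files for DP, CD4SP
#' and Th0, H3K27Ac BED files for DP and CD4SP, the planted-truth table,
#' and a ready-to-run pipeline `config.yaml`. With noise off, the planted
#' construction guarantees that the pipeline's licensed set equals the
#' truth-licensed set exactly.
#'
#' @param config a [synthetic_config()]
#' @param dir output directory (created if needed)
#' @return invisibly, a list with `paths`, `truth` and `config`
#' @export
generate_synthetic_bundle <- function(config = synthetic_config(), dir) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(config$seed)
  n <- config$n_genes

  ## genome geometry: sequential non-overlapping loci, round-robin over
  ## chromosomes, alternating strand
  chrom <- sprintf("chr%d", ((seq_len(n) - 1L) %% config$n_chromosomes) + 1L)
  len <- floor(stats::runif(n, config$gene_length_range[1L],
                            config$gene_length_range[2L] + 1))
  gap <- floor(stats::runif(n, config$intergenic_gap_range[1L],
                            config$intergenic_gap_range[2L] + 1))
  start <- integer(n)
  cursor <- stats::setNames(rep(20000L, config$n_chromosomes),
                            sprintf("chr%d", seq_len(config$n_chromosomes)))
  for (i in seq_len(n)) {
    start[i] <- cursor[chrom[i]]
    cursor[chrom[i]] <- as.integer(start[i] + len[i] + gap[i])
  }
  genes <- data.frame(gene_id = sprintf("G%04d", seq_len(n)),
                      chrom = chrom, start = as.integer(start),
                      end = as.integer(start + len),
                      strand = rep(c("+", "-"), length.out = n),
                      stringsAsFactors = FALSE)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)

  ## planted class labels
  n_per <- round(config$fractions * n)
  perm <- sample.int(n)
  cls <- rep("null", n)
  offset <- 0L
  for (cl in names(n_per)) {
    if (n_per[[cl]] > 0L)
      cls[perm[(offset + 1L):(offset + n_per[[cl]])]] <- cl
    offset <- offset + n_per[[cl]]
  }
  truth <- data.frame(gene_id = genes$gene_id, class = cls,
                      stringsAsFactors = FALSE)

  up_classes <- c("licensed", "no_novel_peak", "no_dev_cre", "no_hmc")
  hmc_classes <- c("licensed", "no_novel_peak", "no_dev_cre", "not_upregulated")
  cre_classes <- c("licensed", "no_novel_peak", "no_hmc", "not_upregulated")
  novel_classes <- c("licensed", "no_dev_cre", "no_hmc", "not_upregulated")

  ## counts: planted per-stage means; base -> target fold change 2^lfc for
  ## upregulated classes with a half-way intermediate stage trajectory
  n_stage <- length(config$stages)
  stage_mult <- 2^(config$lfc * (seq_len(n_stage) - 1L) / (n_stage - 1L))
  mu <- matrix(config$null_mean, nrow = n, ncol = n_stage,
               dimnames = list(genes$gene_id, config$stages))
  expressed <- cls != "null"
  mu[expressed, ] <- config$base_mean
  up <- cls %in% up_classes
  mu[up, ] <- round(config$base_mean * rep(stage_mult, each = sum(up)))
  samples <- as.vector(t(outer(config$stages, seq_len(config$replicates),
                               function(s, r) sprintf("%s_%d", s, r))))
  counts <- matrix(0L, nrow = n, ncol = length(samples),
                   dimnames = list(genes$gene_id, samples))
  for (j in seq_along(samples)) {
    st <- sub("_[^_]+$", "", samples[j])
    m_j <- mu[, st]
    counts[, j] <- if (config$count_noise) {
      as.integer(stats::rnbinom(n, mu = m_j, size = 1 / config$dispersion))
    } else {
      as.integer(round(m_j))
    }
  }

  ## 5hmC tracks: per-bp background everywhere a gene lies; enriched IP
  ## over the bodies of 5hmC-positive genes. A fraction of positive genes
  ## carries the stronger mark in DP (early demethylation), the rest gains
  ## further in CD4SP.
  hmc_pos <- cls %in% hmc_classes
  higher_dp <- rep(FALSE, n)
  pos_idx <- which(hmc_pos)
  if (length(pos_idx) > 0L) {
    n_high <- round(config$frac_hmc_higher_dp * length(pos_idx))
    if (n_high > 0L) higher_dp[sample(pos_idx, n_high)] <- TRUE
  }
  enr <- function(state) {
    e <- rep(0, n)
    strong <- config$hmc_factor
    weak <- config$hmc_factor - 0.5
    if (state == "DP") e[hmc_pos] <- ifelse(higher_dp[hmc_pos], strong, weak)
    else e[hmc_pos] <- ifelse(higher_dp[hmc_pos], weak, strong)
    e
  }
  make_tracks <- function(state) {
    e <- enr(state)
    ord <- order(genes$chrom, genes$start)
    segs <- lapply(ord, function(i) {
      bs <- seq(genes$start[i], genes$end[i] - 1L, by = config$bin_width)
      be <- pmin(bs + config$bin_width, genes$end[i])
      data.frame(chrom = genes$chrom[i], start = as.integer(bs),
                 end = as.integer(be),
                 ip = config$background_value * 2^e[i],
                 input = config$background_value,
                 stringsAsFactors = FALSE)
    })
    all <- do.call(rbind, segs)
    list(ip = signal_track(data.frame(chrom = all$chrom, start = all$start,
                                      end = all$end, value = all$ip)),
         input = signal_track(data.frame(chrom = all$chrom, start = all$start,
                                         end = all$end, value = all$input)))
  }
  tracks <- list(DP = make_tracks("DP"), CD4SP = make_tracks("CD4SP"))

  ## peaks: one jitter offset per planted locus, shared by every peak of
  ## that locus so bounded jitter cannot break planted overlaps
  jit <- function() {
    if (config$peak_jitter == 0L) 0L
    else as.integer(sample(seq(-config$peak_jitter, config$peak_jitter), 1L))
  }
  empty_peaks <- function() genomic_intervals(character(0), integer(0), integer(0))
  dev_atac <- list()
  dev_k27 <- list()
  th0_extra <- list()
  half_pw <- config$peak_width %/% 2L
  for (i in seq_len(n)) {
    if (cls[i] %in% cre_classes || cls[i] == "no_dev_cre") {
      # mid-body accessible site; no_dev_cre gets ATAC without H3K27Ac
      o <- jit()
      mid <- as.integer((genes$start[i] + genes$end[i]) %/% 2L) + o
      atac_iv <- data.frame(chrom = genes$chrom[i], start = mid - half_pw,
                            end = mid + half_pw, strand = ".",
                            name = sprintf("dev_%s", genes$gene_id[i]),
                            score = 100, stringsAsFactors = FALSE)
      dev_atac[[length(dev_atac) + 1L]] <- atac_iv
      if (cls[i] %in% cre_classes) {
        dev_k27[[length(dev_k27) + 1L]] <-
          data.frame(chrom = genes$chrom[i], start = mid - half_pw %/% 2L,
                     end = mid + half_pw + half_pw %/% 2L, strand = ".",
                     name = sprintf("k27_%s", genes$gene_id[i]),
                     score = 100, stringsAsFactors = FALSE)
      }
    }
    if (cls[i] %in% novel_classes) {
      o <- jit()
      if (genes$strand[i] == "+") {
        s <- genes$tss[i] - config$novel_offset - config$novel_width + o
      } else {
        s <- genes$tss[i] + config$novel_offset + o
      }
      th0_extra[[length(th0_extra) + 1L]] <-
        data.frame(chrom = genes$chrom[i], start = as.integer(s),
                   end = as.integer(s + config$novel_width), strand = ".",
                   name = sprintf("novel_%s", genes$gene_id[i]),
                   score = 100, stringsAsFactors = FALSE)
    }
  }
  bind_peaks <- function(lst) {
    if (length(lst) == 0L) return(empty_peaks())
    df <- do.call(rbind, lst)
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  dev_atac_df <- bind_peaks(dev_atac)
  dev_k27_df <- bind_peaks(dev_k27)
  th0_df <- bind_peaks(c(dev_atac, th0_extra))  # activated cells keep developmental accessibility

  ## write the bundle
  paths <- list(
    gene_table = file.path(dir, "genes.tsv"),
    counts = file.path(dir, "counts.tsv"),
    hmc_dp_ip = file.path(dir, "hmc_DP_ip.bedGraph"),
    hmc_dp_input = file.path(dir, "hmc_DP_input.bedGraph"),
    hmc_cd4sp_ip = file.path(dir, "hmc_CD4SP_ip.bedGraph"),
    hmc_cd4sp_input = file.path(dir, "hmc_CD4SP_input.bedGraph"),
    atac_dp = file.path(dir, "atac_DP.bed"),
    atac_cd4sp = file.path(dir, "atac_CD4SP.bed"),
    atac_th0 = file.path(dir, "atac_Th0.bed"),
    k27ac_dp = file.path(dir, "k27ac_DP.bed"),
    k27ac_cd4sp = file.path(dir, "k27ac_CD4SP.bed"),
    truth = file.path(dir, "truth.tsv"),
    config = file.path(dir, "config.yaml"))
  write_gene_table(genes, paths$gene_table)
  write_counts(counts_matrix(counts), paths$counts)
  write_bedgraph(tracks$DP$ip, paths$hmc_dp_ip)
  write_bedgraph(tracks$DP$input, paths$hmc_dp_input)
  write_bedgraph(tracks$CD4SP$ip, paths$hmc_cd4sp_ip)
  write_bedgraph(tracks$CD4SP$input, paths$hmc_cd4sp_input)
  write_bed(peak_set(dev_atac_df, "ATAC", "DP"), paths$atac_dp)
  write_bed(peak_set(dev_atac_df, "ATAC", "CD4SP"), paths$atac_cd4sp)
  write_bed(peak_set(th0_df, "ATAC", "Th0"), paths$atac_th0)
  write_bed(peak_set(dev_k27_df, "H3K27Ac", "DP"), paths$k27ac_dp)
  write_bed(peak_set(dev_k27_df, "H3K27Ac", "CD4SP"), paths$k27ac_cd4sp)
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  pipeline_cfg <- list(
    inputs = list(gene_table = paths$gene_table, counts = paths$counts,
                  hmc = list(DP = list(ip = paths$hmc_dp_ip,
                                       input = paths$hmc_dp_input),
                             CD4SP = list(ip = paths$hmc_cd4sp_ip,
                                          input = paths$hmc_cd4sp_input)),
                  atac = list(DP = paths$atac_dp, CD4SP = paths$atac_cd4sp,
                              Th0 = paths$atac_th0),
                  k27ac = list(DP = paths$k27ac_dp, CD4SP = paths$k27ac_cd4sp)),
    stages = list(base = config$stages[1L],
                  target = config$stages[length(config$stages)],
                  activated = "Th0"),
    thresholds = list(min_count = 10L, lfc_threshold = 1, hmc_threshold = 2,
                      max_tss_dist = 10000L, min_overlap_bp = 1L),
    pseudocount = list(expression = 1, hmc = 1))
  yaml::write_yaml(pipeline_cfg, paths$config)

  invisible(list(paths = paths, truth = truth, config = config))
}
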