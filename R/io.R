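#' Peak sets
#'
#' A `peak_set` couples an interval table with its assay (`ATAC`,
#' `H3K27Ac` or `other`) and cell-state label (e.g. `DP`, `CD4SP`, `Th0`).
#'
#' @param intervals interval data frame (see [genomic_intervals()])
#' @param assay assay label
#' @param state cell-state label
#' @return a `peak_set` object
#' @export
peak_set <- function(intervals, assay, state) {
  if (!is.character(assay) || length(assay) != 1L || !nzchar(assay))
    stop("assay must be a non-empty string", call. = FALSE)
  if (!is.character(state) || length(state) != 1L || !nzchar(state))
    stop("state must be a non-empty string", call. = FALSE)
  validate_intervals(intervals, sprintf("peak set %s/%s", assay, state))
  structure(list(intervals = intervals, assay = assay, state = state),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set: %d peaks, assay=%s, state=%s\n",
              nrow(x$intervals), x$assay, x$state))
  invisible(x)
}

#' @export
length.peak_set <- function(x) nrow(x$intervals)

read_tab_lines <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  list(lines = lines[keep], numbers = which(keep))
}

#' Read a BED3/BED6 file into a peak set
#'
#' Coordinates are 0-based half-open (BED convention). Lines starting with
#' `#` are ignored. Malformed lines (fewer than 3 fields, non-integer or
#' inverted coordinates) raise an error naming the offending line number.
#'
#' @param path BED file path
#' @param assay,state labels attached to the resulting [peak_set()]
#' @param min_score optional minimum score; peaks with a score below it are
#'   dropped (scoreless peaks are kept)
#' @return a `peak_set`
#' @export
read_bed <- function(path, assay = "other", state = "unknown",
                     min_score = NULL) {
  tl <- read_tab_lines(path)
  n <- length(tl$lines)
  if (n == 0L) {
    return(peak_set(genomic_intervals(character(0), integer(0), integer(0)),
                    assay, state))
  }
  fields <- strsplit(tl$lines, "\t", fixed = TRUE)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    ln <- tl$numbers[i]
    if (length(f) < 3L)
      stop(sprintf("%s line %d: expected >= 3 tab-separated fields", path, ln),
           call. = FALSE)
    start <- suppressWarnings(as.integer(f[2L]))
    end <- suppressWarnings(as.integer(f[3L]))
    if (is.na(start) || is.na(end))
      stop(sprintf("%s line %d: non-integer coordinates", path, ln),
           call. = FALSE)
    if (start < 0L || end <= start)
      stop(sprintf("%s line %d: invalid interval [%d, %d)", path, ln, start, end),
           call. = FALSE)
    strand <- if (length(f) >= 6L && f[6L] %in% c("+", "-")) f[6L] else "."
    out[[i]] <- list(chrom = f[1L], start = start, end = end,
                     name = if (length(f) >= 4L) f[4L] else NA_character_,
                     score = if (length(f) >= 5L)
                       suppressWarnings(as.numeric(f[5L])) else NA_real_,
                     strand = strand)
  }
  df <- data.frame(chrom = vapply(out, `[[`, "", "chrom"),
                   start = vapply(out, `[[`, 0L, "start"),
                   end = vapply(out, `[[`, 0L, "end"),
                   strand = vapply(out, `[[`, "", "strand"),
                   name = vapply(out, `[[`, "", "name"),
                   score = vapply(out, `[[`, 0, "score"),
                   stringsAsFactors = FALSE)
  if (!is.null(min_score)) {
    df <- df[is.na(df$score) | df$score >= min_score, , drop = FALSE]
    rownames(df) <- NULL
  }
  peak_set(df, assay, state)
}

#' Write a peak set as BED6
#'
#' @param peaks a [peak_set()]
#' @param path output path
#' @export
write_bed <- function(peaks, path) {
  stopifnot(inherits(peaks, "peak_set"))
  df <- peaks$intervals
  if (nrow(df) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  name <- ifelse(is.na(df$name), ".", df$name)
  score <- ifelse(is.na(df$score), "0", format_num(df$score))
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                   df$chrom, df$start, df$end, name, score, df$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene model table
#'
#' TSV with header `gene_id`, `chrom`, `start`, `end`, `strand`
#' (0-based half-open gene bodies; strand must be `+` or `-`). The TSS is
#' derived from strand: `start` for `+` genes, `end` for `-` genes.
#'
#' @param path TSV file path
#' @return data.frame with columns gene_id, chrom, start, end, strand, tss
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#",
                          colClasses = c("character", "character",
                                         "integer", "integer", "character"))
  required <- c("gene_id", "chrom", "start", "end", "strand")
  if (!identical(names(df)[seq_along(required)], required))
    stop(sprintf("gene table must have header: %s", paste(required, collapse = ", ")),
         call. = FALSE)
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup) > 0L)
    stop(sprintf("duplicate gene_id: %s", dup[1L]), call. = FALSE)
  badstr <- which(!df$strand %in% c("+", "-"))
  if (length(badstr) > 0L)
    stop(sprintf("gene %s: strand must be + or - (got '%s')",
                 df$gene_id[badstr[1L]], df$strand[badstr[1L]]), call. = FALSE)
  validate_intervals(df, "gene table")
  df$tss <- ifelse(df$strand == "+", df$start, df$end)
  df
}

#' Write a gene model table
#' @param genes gene table (see [read_gene_table()])
#' @param path output path
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes[, c("gene_id", "chrom", "start", "end", "strand")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a stage-labelled counts matrix
#'
#' TSV whose first column is `gene_id` and remaining columns are named
#' `<stage>_<replicate>`. Entries must be non-negative integers.
#'
#' @param path TSV file path
#' @return a `counts_matrix` object: list with `counts` (integer matrix,
#'   genes x samples), `stage` (character vector per sample), and
#'   `normalized` flag
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE)
  if (names(df)[1L] != "gene_id")
    stop("counts table must start with a gene_id column", call. = FALSE)
  samples <- names(df)[-1L]
  bad <- samples[!grepl("^.+_[^_]+$", samples)]
  if (length(bad) > 0L)
    stop(sprintf("sample column '%s' does not match <stage>_<replicate>", bad[1L]),
         call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m) || anyNA(m))
    stop("counts must be numeric", call. = FALSE)
  if (any(m < 0))
    stop("counts must be non-negative", call. = FALSE)
  if (any(m != floor(m)))
    stop("raw counts must be integers", call. = FALSE)
  storage.mode(m) <- "integer"
  rownames(m) <- df$gene_id
  counts_matrix(m, stage = sub("_[^_]+$", "", samples))
}

#' Construct a counts matrix object
#'
#' @param counts numeric matrix, genes x samples, with gene ids as rownames
#'   and sample labels as colnames
#' @param stage character vector assigning each sample to a stage; derived
#'   from column names (`<stage>_<replicate>`) when missing
#' @param normalized whether values are normalized (reals) rather than raw
#'   integer counts
#' @return a `counts_matrix`
#' @export
counts_matrix <- function(counts, stage = NULL, normalized = FALSE) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  if (is.null(stage)) {
    if (is.null(colnames(counts)))
      stop("stage labels required when counts has no column names", call. = FALSE)
    stage <- sub("_[^_]+$", "", colnames(counts))
  }
  if (length(stage) != ncol(counts))
    stop("one stage label per sample required", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  structure(list(counts = counts, stage = as.character(stage),
                 normalized = isTRUE(normalized)),
            class = "counts_matrix")
}

#' @export
print.counts_matrix <- function(x, ...) {
  st <- table(x$stage)
  cat(sprintf("counts_matrix: %d genes x %d samples (%s)%s\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s:%d", names(st), st), collapse = ", "),
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Write a counts matrix as TSV
#' @param m a `counts_matrix`
#' @param path output path
#' @export
write_counts <- function(m, path) {
  stopifnot(inherits(m, "counts_matrix"))
  df <- data.frame(gene_id = rownames(m$counts), m$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' 4-column bedGraph (chrom, start, end, value), 0-based half-open. Segments
#' on a chromosome must be non-overlapping; values must be non-negative.
#' Uncovered positions are treated as signal 0.
#'
#' @param path bedGraph file path
#' @return a `signal_track`: data.frame (chrom, start, end, value) sorted by
#'   chrom then start
#' @export
read_bedgraph <- function(path) {
  tl <- read_tab_lines(path)
  n <- length(tl$lines)
  if (n == 0L) {
    return(signal_track(data.frame(chrom = character(0), start = integer(0),
                                   end = integer(0), value = numeric(0))))
  }
  fields <- strsplit(tl$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L)) {
    i <- which(nf < 4L)[1L]
    stop(sprintf("%s line %d: expected 4 tab-separated fields", path, tl$numbers[i]),
         call. = FALSE)
  }
  df <- data.frame(chrom = vapply(fields, `[[`, "", 1L),
                   start = suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L))),
                   end = suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L))),
                   value = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L))),
                   stringsAsFactors = FALSE)
  bad <- which(is.na(df$start) | is.na(df$end) | is.na(df$value))
  if (length(bad) > 0L)
    stop(sprintf("%s line %d: non-numeric field", path, tl$numbers[bad[1L]]),
         call. = FALSE)
  signal_track(df)
}

#' Construct and validate a signal track
#' @param df data.frame with chrom, start, end, value
#' @return validated, sorted `signal_track`
#' @export
signal_track <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("chrom", "start", "end", "value") %in% names(df)))
  df <- df[, c("chrom", "start", "end", "value")]
  df$strand <- rep(".", nrow(df))
  validate_intervals(df, "signal track")
  df$strand <- NULL
  if (any(df$value < 0))
    stop("signal track values must be non-negative", call. = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  # overlap check within each chromosome on the sorted table
  if (nrow(df) > 1L) {
    same <- df$chrom[-1L] == df$chrom[-nrow(df)]
    ovl <- df$start[-1L] < df$end[-nrow(df)]
    bad <- which(same & ovl)
    if (length(bad) > 0L)
      stop(sprintf("overlapping segments on %s at %d", df$chrom[bad[1L]],
                   df$start[bad[1L] + 1L]), call. = FALSE)
  }
  class(df) <- c("signal_track", "data.frame")
  df
}

#' Write a signal track as bedGraph
#' @param track a `signal_track`
#' @param path output path
#' @export
write_bedgraph <- function(track, path) {
  if (nrow(track) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  writeLines(sprintf("%s\t%d\t%d\t%s", track$chrom, track$start, track$end,
                     format_num(track$value)), path)
  invisible(path)
}

#' Read a term-to-gene annotation map
#'
#' Two-column TSV (`term_id`, `gene_id`), one gene membership per row, with
#' a header line.
#'
#' @param path TSV file path
#' @return named list mapping term_id to character vectors of gene ids
#' @export
read_term_map <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("term_id", "gene_id") %in% names(df)))
    stop("term map must have columns term_id, gene_id", call. = FALSE)
  lapply(split(df$gene_id, df$term_id), unique)
}

# fixed-notation numeric formatting shared by all writers (determinism)
format_num <- function(x) {
  out <- trimws(formatC(x, format = "fg", digits = 10))
  has_dot <- grepl(".", out, fixed = TRUE)
  out[has_dot] <- sub("\\.?0+$", "", out[has_dot])
  out
}
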