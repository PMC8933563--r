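#' Genomic interval tables
#'
#' Intervals are plain data frames in BED convention: 0-based, half-open
#' `[start, end)`. Columns: `chrom` (character), `start`, `end` (integers),
#' `strand` (one of `+`, `-`, `.`), and optional `name`, `score`.
#'
#' @param chrom character vector of chromosome names
#' @param start,end integer vectors, 0-based half-open
#' @param strand strand characters; defaults to `"."`
#' @param name optional labels
#' @param score optional numeric scores
#' @return a data.frame of validated intervals
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".",
                              name = NA_character_, score = NA_real_) {
  n <- length(chrom)
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   strand = rep_len(as.character(strand), n),
                   name = rep_len(as.character(name), n),
                   score = rep_len(as.numeric(score), n),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df, context = "interval") {
  stopifnot(is.data.frame(df))
  required <- c("chrom", "start", "end", "strand")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s table lacks column(s): %s", context,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0L) return(invisible(df))
  if (anyNA(df$start) || anyNA(df$end)) {
    stop(sprintf("%s: non-integer coordinates", context), call. = FALSE)
  }
  bad <- which(df$start < 0L | df$end <= df$start)
  if (length(bad) > 0L) {
    stop(sprintf("%s: invalid coordinates at row %d (start=%s, end=%s); need 0 <= start < end",
                 context, bad[1L], df$start[bad[1L]], df$end[bad[1L]]), call. = FALSE)
  }
  badstr <- which(!df$strand %in% c("+", "-", "."))
  if (length(badstr) > 0L) {
    stop(sprintf("%s: invalid strand '%s' at row %d (must be +, - or .)",
                 context, df$strand[badstr[1L]], badstr[1L]), call. = FALSE)
  }
  invisible(df)
}

#' Overlap length between two intervals
#'
#' Half-open overlap in bp: `max(0, min(end) - max(start))` when the
#' chromosomes match, 0 otherwise. Adjacent intervals (`a$end == b$start`)
#' do not overlap.
#'
#' @param a,b single-interval lists or one-row data frames with
#'   `chrom`, `start`, `end`
#' @return non-negative integer bp count
#' @export
overlap_length <- function(a, b) {
  if (a$chrom != b$chrom) return(0L)
  max(0L, as.integer(min(a$end, b$end) - max(a$start, b$start)))
}

#' Test whether two intervals overlap by at least `min_bp`
#'
#' @inheritParams overlap_length
#' @param min_bp minimum overlap in bp (>= 1)
#' @return logical
#' @export
overlaps <- function(a, b, min_bp = 1L) {
  if (min_bp < 1L) stop("min_bp must be >= 1", call. = FALSE)
  overlap_length(a, b) >= min_bp
}

#' Distance from an interval to a point
#'
#' 0 if `pos` lies inside the half-open interval, otherwise the distance to
#' the nearest covered base (`start` or `end - 1`). The caller is responsible
#' for only comparing positions on the interval's chromosome.
#'
#' @param a single interval (list or one-row data frame)
#' @param pos 0-based position in bp
#' @return non-negative bp distance
#' @export
distance_to_point <- function(a, pos) {
  if (pos >= a$start && pos < a$end) return(0L)
  as.integer(min(abs(pos - (a$end - 1L)), abs(pos - a$start)))
}

#' Build a searchable index over an interval table
#'
#' The index supports exact overlap queries (results identical to an
#' exhaustive all-pairs comparison). Backed by the nested containment lists
#' of \pkg{GenomicRanges}.
#'
#' @param df interval data frame (see [genomic_intervals()])
#' @return an `interval_index` object
#' @export
build_index <- function(df) {
  validate_intervals(df, "index input")
  gr <- intervals_to_granges(df)
  structure(list(gr = gr, table = df), class = "interval_index")
}

#' Query an interval index
#'
#' @param index an `interval_index` from [build_index()]
#' @param probe a single interval (list or one-row data frame)
#' @param min_bp minimum overlap in bp
#' @return the rows of the indexed table overlapping the probe (order
#'   unspecified); zero-row data frame when nothing overlaps
#' @export
query_index <- function(index, probe, min_bp = 1L) {
  stopifnot(inherits(index, "interval_index"))
  if (min_bp < 1L) stop("min_bp must be >= 1", call. = FALSE)
  if (length(index$gr) == 0L) return(index$table[0L, , drop = FALSE])
  probe_gr <- GenomicRanges::GRanges(
    probe$chrom, IRanges::IRanges(start = probe$start + 1L, end = probe$end))
  hits <- GenomicRanges::findOverlaps(probe_gr, index$gr,
                                      minoverlap = as.integer(min_bp))
  index$table[S4Vectors::subjectHits(hits), , drop = FALSE]
}

# 0-based half-open -> 1-based closed GRanges
intervals_to_granges <- function(df) {
  if (nrow(df) == 0L) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

# vectorised overlap length of one probe against an interval table
overlap_length_vec <- function(df, probe) {
  if (nrow(df) == 0L) return(integer(0L))
  same <- df$chrom == probe$chrom
  ol <- pmin(df$end, probe$end) - pmax(df$start, probe$start)
  as.integer(ifelse(same, pmax(0L, ol), 0L))
}
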