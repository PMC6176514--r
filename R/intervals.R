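#' Construct a table of genomic intervals
#'
#' All coordinates in this package are 0-based half-open (BED-native):
#' `start` is the first base covered, `end` is one past the last. A single
#' internal convention removes the off-by-one drift that creeps in when
#' 1-based formats (SNP tables, GTF) are mixed with BED-family files; those
#' formats are converted on read.
#'
#' @param chrom character vector of chromosome names (compared verbatim; no
#'   "chr" normalisation).
#' @param start,end integer-like vectors, 0-based half-open; `end > start`.
#' @param strand one of `"+"`, `"-"`, `"*"` (unstranded), recycled.
#' @return a `data.frame` with columns `chrom`, `start`, `end`, `strand`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = "*") {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(is.na(chrom)) || any(!nzchar(chrom))) {
    stop("chrom must be non-empty")
  }
  if (any(start < 0)) stop("start must be >= 0")
  if (any(end <= start)) stop("end must be > start (half-open, non-empty)")
  strand <- rep_len(as.character(strand), length(chrom))
  if (!all(strand %in% c("+", "-", "*"))) stop("strand must be one of +, -, *")
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

# strand-blind overlap join on interval tables; disjoint chromosome sets are
# a legitimate no-hit case, not worth a seqlevel warning
find_hits <- function(a, b) {
  suppressWarnings(
    GenomicRanges::findOverlaps(as_granges(a), as_granges(b),
                                ignore.strand = TRUE))
}

# data.frame (0-based half-open) -> GRanges (1-based closed). Internal bridge
# to the IRanges/GenomicRanges machinery used for all overlap joins.
as_granges <- function(df) {
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  strand[!strand %in% c("+", "-")] <- "*"
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end),
    strand = strand
  )
}

#' Test whether two genomic intervals overlap
#'
#' Half-open semantics: intervals overlap iff they share at least one base,
#' i.e. same chromosome and `a$start < b$end && b$start < a$end`. Abutting
#' intervals (`a$end == b$start`) do not overlap. Vectorised with recycling.
#'
#' @param a,b interval tables as from [genomic_intervals()] (or any
#'   data.frame with `chrom`, `start`, `end`).
#' @return logical vector.
#' @export
overlaps <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  a$chrom[ai] == b$chrom[bi] &
    a$start[ai] < b$end[bi] &
    b$start[bi] < a$end[ai]
}

#' Symmetric window around a point
#'
#' Returns the interval covering every base within `flank` bp of the point,
#' closed on both sides: `[max(0, pos0 - flank), pos0 + flank + 1)`. Used for
#' the +/- 1 kb windows around CTCF high-confidence peak summits.
#'
#' @param chrom chromosome name(s).
#' @param pos0 0-based point position(s).
#' @param flank positive flank size in bp.
#' @return interval table with one row per point; always contains the point.
#' @export
window_around <- function(chrom, pos0, flank) {
  if (any(flank <= 0)) stop("flank must be > 0")
  genomic_intervals(chrom, pmax(0, pos0 - flank), pos0 + flank + 1)
}

#' Keep query records overlapping a reference set
#'
#' Membership filter in the style of `bedtools intersect -wa -u`: each query
#' record is returned at most once if it shares >= 1 bp with any reference
#' interval. With `keep_full_query = FALSE` the surviving records are clipped
#' to the extent of their intersection with the merged reference coverage
#' (summit offsets are dropped in that mode, which is why membership
#' semantics are the default: downstream steps need original summits).
#'
#' @param query data.frame of intervals (any extra columns carried through).
#' @param reference data.frame of intervals.
#' @param keep_full_query keep original query coordinates (default) or clip.
#' @param require_sorted if `TRUE`, error (naming the first offending row)
#'   unless both inputs are sorted by (chrom, start).
#' @return subset of `query`, in input order.
#' @export
filter_overlapping <- function(query, reference, keep_full_query = TRUE,
                               require_sorted = FALSE) {
  if (require_sorted) {
    check_sorted(query, "query")
    check_sorted(reference, "reference")
  }
  if (nrow(query) == 0 || nrow(reference) == 0) return(query[0, , drop = FALSE])
  hits <- find_hits(query, reference)
  keep <- sort(unique(S4Vectors::queryHits(hits)))
  out <- query[keep, , drop = FALSE]
  if (!keep_full_query && nrow(out) > 0) {
    merged <- merge_intervals(reference)
    h2 <- find_hits(out, merged)
    qh <- S4Vectors::queryHits(h2)
    sh <- S4Vectors::subjectHits(h2)
    lo <- tapply(pmax(out$start[qh], merged$start[sh]), qh, min)
    hi <- tapply(pmin(out$end[qh], merged$end[sh]), qh, max)
    idx <- as.integer(names(lo))
    out$start[idx] <- as.numeric(lo)
    out$end[idx] <- as.numeric(hi)
    out$summit_offset <- NULL
  }
  rownames(out) <- NULL
  out
}

check_sorted <- function(df, what) {
  if (nrow(df) < 2) return(invisible(TRUE))
  o <- order(df$chrom, df$start)
  bad <- which(o != seq_len(nrow(df)))
  if (length(bad) > 0) {
    stop(sprintf("%s is not sorted by (chrom, start): record %d (%s:%d-%d) is out of order",
                 what, bad[1], df$chrom[bad[1]], df$start[bad[1]], df$end[bad[1]]))
  }
  invisible(TRUE)
}

#' Merge overlapping intervals
#'
#' Collapses a set of intervals to its union coverage (strand-blind).
#'
#' @param df interval table.
#' @return interval table of disjoint merged intervals, sorted.
#' @export
merge_intervals <- function(df) {
  if (nrow(df) == 0) return(genomic_intervals("chrUn", 0, 1)[0, ])
  red <- GenomicRanges::reduce(as_granges(df), ignore.strand = TRUE)
  genomic_intervals(as.character(GenomicRanges::seqnames(red)),
                    GenomicRanges::start(red) - 1,
                    GenomicRanges::end(red))
}

# Number of bases of `interval` (single row) covered by >=1 record of `df`.
covered_bases <- function(interval, df) {
  if (nrow(df) == 0) return(0)
  m <- merge_intervals(df[df$chrom == interval$chrom, , drop = FALSE])
  if (nrow(m) == 0) return(0)
  lo <- pmax(m$start, interval$start)
  hi <- pmin(m$end, interval$end)
  sum(pmax(0, hi - lo))
}

# Gap distance between interval rows of `df` and a point; 0 when the point
# lies inside the interval.
point_distance <- function(df, chrom, pos0) {
  d <- pmax(df$start - pos0, pos0 - (df$end - 1), 0)
  d[df$chrom != chrom] <- Inf
  d
}

sort_intervals <- function(df) {
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}
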