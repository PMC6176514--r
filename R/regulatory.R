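# Enhancer-desert detection inside risk loops, repressive-mark coverage,
# target-gene prediction and enhancer-adoption candidate nomination.

#' Detect enhancer deserts inside risk loops
#'
#' The loop interior is the region between the inner anchor edges
#' (`[end1, start2)`): the anchor bins themselves are excluded since the risk
#' CTCF site sits in an anchor, not in the desert. Per loop, H3K27Ac HC peaks
#' from any roster dataset overlapping the interior are counted;
#' `is_desert` requires zero interior peaks and an interior of at least
#' `min_desert_len` bp (observed deserts are hundreds of kb; the default
#' floor of 100 kb keeps short loop interiors from qualifying trivially).
#'
#' @param risk_loops data.frame of loops (canonical anchor columns).
#' @param k27ac_sets list of H3K27Ac `hc_peak_set` objects (the union of the
#'   roster is used).
#' @param min_desert_len minimum interior length in bp.
#' @return `risk_loops` with `interior_start`, `interior_end`,
#'   `interior_len`, `n_k27ac_interior`, `is_desert` appended.
#' @export
find_deserts <- function(risk_loops, k27ac_sets, min_desert_len = 100000) {
  peaks <- do.call(rbind, lapply(k27ac_sets, function(s)
    s$peaks[, c("chrom", "start", "end")]))
  if (is.null(peaks)) peaks <- genomic_intervals("x", 0, 1)[0, ]
  out <- risk_loops
  out$interior_start <- out$end1
  out$interior_end <- out$start2
  out$interior_len <- pmax(0, out$interior_end - out$interior_start)
  out$n_k27ac_interior <- 0L
  ok <- out$interior_len > 0
  if (any(ok) && nrow(peaks) > 0) {
    interiors <- genomic_intervals(out$chrom1[ok], out$interior_start[ok],
                                   out$interior_end[ok])
    h <- find_hits(interiors, peaks)
    counts <- table(factor(S4Vectors::queryHits(h), seq_len(nrow(interiors))))
    out$n_k27ac_interior[ok] <- as.integer(counts)
  }
  out$is_desert <- out$n_k27ac_interior == 0 &
    out$interior_len >= min_desert_len
  out
}

#' Fraction of an interval covered by a repressive mark
#'
#' Overlapping peaks are merged before measuring, so double-covered bases
#' count once; the result is merged base-pair coverage of the interval
#' divided by its length, in [0, 1].
#'
#' @param interior single-row interval table.
#' @param k27me3 peak table (H3K27me3 or any mark).
#' @return numeric fraction.
#' @export
repressive_coverage <- function(interior, k27me3) {
  len <- interior$end - interior$start
  if (len <= 0) {
    warning("zero-length interior; coverage reported as 0")
    return(0)
  }
  covered_bases(interior, k27me3) / len
}

#' Predict target genes of a risk site
#'
#' Union of (a) genes whose TSS lies inside the full span
#' `[start1, end2)` of any risk loop (`basis = "within_loop"`) and (b) genes
#' whose TSS is within +/- `window` bp of the site
#' (`basis = "within_window"`); deduplicated with `within_loop` taking
#' precedence. TSS position (not the gene span) decides membership so calls
#' at loop edges are unambiguous.
#'
#' @param site list/data.frame with `chrom`, `pos0`.
#' @param risk_loops data.frame of risk loops.
#' @param genes a `gene_models` object.
#' @param window flank in bp (default 1 Mb); `window = 0` returns only
#'   within-loop genes.
#' @return data.frame with `gene_id`, `gene_name`, `tss_pos0`, `basis`,
#'   `distance_bp` (TSS to site), sorted by distance.
#' @export
predict_targets <- function(site, risk_loops, genes, window = 1e6) {
  g <- genes$genes
  on_chrom <- g$chrom == site$chrom
  in_loop <- rep(FALSE, nrow(g))
  for (i in seq_len(nrow(risk_loops))) {
    in_loop <- in_loop | (g$chrom == risk_loops$chrom1[i] &
                            g$tss_pos0 >= risk_loops$start1[i] &
                            g$tss_pos0 < risk_loops$end2[i])
  }
  dist <- abs(g$tss_pos0 - site$pos0)
  in_window <- on_chrom & window > 0 & dist <= window
  keep <- in_loop | in_window
  out <- data.frame(gene_id = g$gene_id[keep], gene_name = g$gene_name[keep],
                    tss_pos0 = g$tss_pos0[keep],
                    basis = ifelse(in_loop[keep], "within_loop",
                                   "within_window"),
                    distance_bp = dist[keep], stringsAsFactors = FALSE)
  out <- out[order(out$distance_bp, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Nominate enhancer-adoption candidates after an anchor deletion
#'
#' When a repressive anchor is deleted, the caged promoter may adopt a
#' pre-existing enhancer outside the desert. Candidates are H3K27Ac HC peaks
#' (union over the roster, merged across datasets) that do not overlap the
#' desert interior, ranked by gap distance to the deleted site; each is
#' flagged when it contains a risk SNP carrying acetylation-stage evidence
#' (in a DHS and H3K27Ac-positive in >= 1 dataset).
#'
#' @param deleted_site list/data.frame with `chrom`, `pos0`.
#' @param desert single row of a [find_deserts()] result.
#' @param k27ac_sets list of H3K27Ac `hc_peak_set` objects.
#' @param risk_snps an `annotated_snps` object (may be `NULL`; then the risk
#'   flag is `NA`).
#' @param max_distance search radius in bp around the deleted site.
#' @return data.frame of candidates with `rank`, `distance_bp`,
#'   `contains_risk_snp`, nearest first.
#' @export
adoption_candidates <- function(deleted_site, desert, k27ac_sets,
                                risk_snps = NULL, max_distance = 2e6) {
  peaks <- do.call(rbind, lapply(k27ac_sets, function(s)
    s$peaks[, c("chrom", "start", "end")]))
  if (is.null(peaks) || nrow(peaks) == 0) return(empty_candidates())
  peaks <- merge_intervals(peaks[peaks$chrom == deleted_site$chrom, ,
                                 drop = FALSE])
  if (nrow(peaks) == 0) return(empty_candidates())
  interior <- data.frame(chrom = desert$chrom1, start = desert$interior_start,
                         end = desert$interior_end)
  if (interior$end > interior$start) {
    outside <- !(overlaps(peaks, interior[rep(1, nrow(peaks)), ]))
    peaks <- peaks[outside, , drop = FALSE]
  }
  if (nrow(peaks) == 0) return(empty_candidates())
  peaks$distance_bp <- point_distance(peaks, deleted_site$chrom,
                                      deleted_site$pos0)
  peaks <- peaks[peaks$distance_bp <= max_distance, , drop = FALSE]
  if (nrow(peaks) == 0) return(empty_candidates())
  if (!is.null(risk_snps)) {
    s <- risk_snps$snps
    stage <- s$in_dhs & rowSums(risk_snps$k27ac_hits) > 0
    pos <- s$pos0[stage & s$chrom == deleted_site$chrom]
    peaks$contains_risk_snp <- vapply(seq_len(nrow(peaks)), function(i)
      any(pos >= peaks$start[i] & pos < peaks$end[i]), logical(1))
  } else {
    peaks$contains_risk_snp <- NA
  }
  peaks <- peaks[order(peaks$distance_bp), , drop = FALSE]
  peaks$rank <- seq_len(nrow(peaks))
  rownames(peaks) <- NULL
  peaks[, c("rank", "chrom", "start", "end", "distance_bp",
            "contains_risk_snp")]
}

empty_candidates <- function() {
  data.frame(rank = integer(0), chrom = character(0), start = numeric(0),
             end = numeric(0), distance_bp = numeric(0),
             contains_risk_snp = logical(0), stringsAsFactors = FALSE)
}
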