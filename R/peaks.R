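# High-confidence peak derivation from replicate pairs and HOMER-style
# genomic-context classification against gene models.

#' High-confidence peak set
#'
#' A set of ChIP-seq peaks reproduced in both biological replicates of one
#' mark / cell line / condition, with a dataset label used as the roster key
#' throughout the SNP funnel.
#'
#' @param peaks peak table (narrowPeak schema); sorted by (chrom, start) on
#'   construction.
#' @param mark one of `"H3K27Ac"`, `"CTCF"`, `"H3K27me3"`, `"DHS"`.
#' @param cell_line cell line name.
#' @param condition growth condition (e.g. `"DHT"` or `""`).
#' @param dataset roster label; defaults to `cell_line` plus condition.
#' @return object of class `hc_peak_set`.
#' @export
hc_peak_set <- function(peaks, mark, cell_line, condition = "",
                        dataset = NULL) {
  if (is.null(dataset)) {
    dataset <- if (nzchar(condition)) paste(cell_line, condition, sep = "_")
               else cell_line
  }
  structure(list(peaks = sort_intervals(peaks), mark = mark,
                 cell_line = cell_line, condition = condition,
                 dataset = dataset),
            class = "hc_peak_set")
}

#' @export
print.hc_peak_set <- function(x, ...) {
  cat(sprintf("hc_peak_set %s [%s]: %d peaks\n", x$dataset, x$mark,
              nrow(x$peaks)))
  invisible(x)
}

#' Derive high-confidence peaks from a replicate pair
#'
#' A peak is high-confidence (HC) when it is present in both replicates,
#' operationalised as >= 1 bp overlap with a partner-replicate peak. By
#' default the reported coordinates (and summit offsets) are those of
#' replicate 1; `coords = "merged"` instead reports the union span of each
#' replicate-1 peak with all its replicate-2 partners (summits dropped).
#'
#' @param rep1,rep2 peak tables from the two replicates (same mark and cell
#'   line; a mismatch in their `mark`/`cell_line` tags is an error).
#' @param coords `"rep1"` (default) or `"merged"`.
#' @param mark,cell_line,condition,dataset passed to [hc_peak_set()];
#'   defaulting to the tags on `rep1`.
#' @return an `hc_peak_set`; always `|HC| <= |rep1|`.
#' @export
derive_hc_peaks <- function(rep1, rep2, coords = c("rep1", "merged"),
                            mark = NULL, cell_line = NULL, condition = "",
                            dataset = NULL) {
  coords <- match.arg(coords)
  tag1 <- unique(stats::na.omit(c(rep1$mark)))
  tag2 <- unique(stats::na.omit(c(rep2$mark)))
  if (length(tag1) == 1 && length(tag2) == 1 && tag1 != tag2) {
    stop("replicate mark mismatch: ", tag1, " vs ", tag2)
  }
  cl1 <- unique(stats::na.omit(c(rep1$cell_line)))
  cl2 <- unique(stats::na.omit(c(rep2$cell_line)))
  if (length(cl1) == 1 && length(cl2) == 1 && cl1 != cl2) {
    stop("replicate cell-line mismatch: ", cl1, " vs ", cl2)
  }
  if (is.null(mark)) mark <- if (length(tag1) == 1) tag1 else NA_character_
  if (is.null(cell_line)) {
    cell_line <- if (length(cl1) == 1) cl1 else NA_character_
  }
  hc <- filter_overlapping(rep1, rep2, keep_full_query = TRUE)
  if (coords == "merged" && nrow(hc) > 0) {
    hits <- find_hits(hc, rep2)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    hc$start <- pmin(hc$start, as.numeric(
      tapply(rep2$start[sh], qh, min)[as.character(seq_len(nrow(hc)))]))
    hc$end <- pmax(hc$end, as.numeric(
      tapply(rep2$end[sh], qh, max)[as.character(seq_len(nrow(hc)))]))
    hc$summit_offset <- NA_real_
  }
  hc_peak_set(hc, mark = mark, cell_line = cell_line, condition = condition,
              dataset = dataset)
}

CONTEXT_LEVELS <- c("promoter", "exon", "TTS", "intron", "intergenic")

#' Classify genomic context of intervals against gene models
#'
#' HOMER-style assignment with the category set reduced to
#' promoter > exon > TTS > intron > intergenic (fixed priority). Promoter and
#' TTS windows are strand-aware: the promoter spans `promoter_upstream` bp
#' upstream to `promoter_downstream` bp downstream of the TSS; the TTS window
#' spans `tts_flank` bp either side of the transcription end site. Ties
#' across genes at the winning category are broken by the smallest distance
#' from the query midpoint to the TSS.
#'
#' @param query interval table.
#' @param genes a `gene_models` object.
#' @param promoter_upstream,promoter_downstream,tts_flank window sizes in bp.
#' @return data.frame with `category` (factor over the five levels) and
#'   `gene_id` (`NA` for intergenic).
#' @export
classify_context <- function(query, genes, promoter_upstream = 1000,
                             promoter_downstream = 100, tts_flank = 1000) {
  n <- nrow(query)
  out <- data.frame(category = factor(rep("intergenic", n), CONTEXT_LEVELS),
                    gene_id = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  g <- genes$genes
  if (n == 0 || nrow(g) == 0) return(out)

  plus <- g$strand == "+"
  prom <- genomic_intervals(
    g$chrom,
    pmax(0, ifelse(plus, g$tss_pos0 - promoter_upstream,
                   g$tss_pos0 - promoter_downstream + 1)),
    ifelse(plus, g$tss_pos0 + promoter_downstream,
           g$tss_pos0 + promoter_upstream + 1))
  tts <- genomic_intervals(g$chrom, pmax(0, g$tes_pos0 - tts_flank),
                           g$tes_pos0 + tts_flank + 1)
  body <- genomic_intervals(g$chrom, g$start, g$end)

  qgr <- as_granges(query)
  qmid <- floor((query$start + query$end) / 2)

  hit_table <- function(regions, gene_idx, category) {
    h <- suppressWarnings(
      GenomicRanges::findOverlaps(qgr, as_granges(regions),
                                  ignore.strand = TRUE))
    data.frame(q = S4Vectors::queryHits(h),
               g = gene_idx[S4Vectors::subjectHits(h)],
               category = rep(category, length(h)))
  }
  cand <- rbind(
    hit_table(prom, seq_len(nrow(g)), "promoter"),
    if (nrow(genes$exons) > 0)
      hit_table(genomic_intervals(genes$exons$chrom, genes$exons$start,
                                  genes$exons$end),
                match(genes$exons$gene_id, g$gene_id), "exon"),
    hit_table(tts, seq_len(nrow(g)), "TTS"),
    hit_table(body, seq_len(nrow(g)), "intron")
  )
  if (nrow(cand) == 0) return(out)
  cand$prio <- match(cand$category, CONTEXT_LEVELS)
  cand$tss_dist <- abs(qmid[cand$q] - g$tss_pos0[cand$g])
  cand <- cand[order(cand$q, cand$prio, cand$tss_dist), ]
  best <- cand[!duplicated(cand$q), ]
  out$category[best$q] <- best$category
  out$gene_id[best$q] <- g$gene_id[best$g]
  out
}

#' Summarise genomic-context composition of HC peak sets
#'
#' One row per HC set with counts and fractions per context category;
#' fractions sum to 1 and counts sum to the number of peaks.
#'
#' @param hc_sets list of `hc_peak_set` objects.
#' @param genes a `gene_models` object.
#' @param ... passed to [classify_context()].
#' @return data.frame with `dataset`, `mark`, `n_peaks`, then
#'   `n_<category>` and `frac_<category>` columns.
#' @export
summarize_peak_classes <- function(hc_sets, genes, ...) {
  rows <- lapply(hc_sets, function(set) {
    n <- nrow(set$peaks)
    if (n == 0) {
      warning("empty HC set: ", set$dataset)
      counts <- stats::setNames(rep(0L, length(CONTEXT_LEVELS)),
                                CONTEXT_LEVELS)
      fracs <- counts * 0
    } else {
      cls <- classify_context(set$peaks, genes, ...)
      counts <- table(cls$category)
      fracs <- as.numeric(counts) / n
    }
    out <- data.frame(dataset = set$dataset, mark = set$mark, n_peaks = n,
                      stringsAsFactors = FALSE)
    for (i in seq_along(CONTEXT_LEVELS)) {
      out[[paste0("n_", CONTEXT_LEVELS[i])]] <- as.integer(counts[i])
      out[[paste0("frac_", CONTEXT_LEVELS[i])]] <- as.numeric(fracs[i])
    }
    out
  })
  do.call(rbind, rows)
}
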