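# Loop filtering, anchor association, cross-dataset support and convergent
# CTCF motif orientation. Loop span is measured midpoint-to-midpoint of the
# two anchors: anchors are typically fixed-width matrix bins, so midpoints
# are stable under small changes in bin boundaries.

#' Anchor midpoint-to-midpoint span of loops
#' @param loops canonical loop table (see [read_bedpe()]).
#' @return numeric vector, bp.
#' @export
loop_span <- function(loops) {
  floor((loops$start2 + loops$end2) / 2) - floor((loops$start1 + loops$end1) / 2)
}

#' Filter loops by span and significance
#'
#' Keeps intra-chromosomal loops with `min_span <= span < max_span` and
#' `q_value < max_q` (strict). Inter-chromosomal records are rejected and
#' their count reported in a message; `NA` q-values are treated as passing
#' with a warning (supports interaction datasets whose loops were
#' pre-filtered upstream).
#'
#' @param loops loop table.
#' @param min_span,max_span span bounds in bp (defaults 50 kb and 10 Mb).
#' @param max_q q-value threshold (default 0.05).
#' @return filtered loop table.
#' @export
filter_loops <- function(loops, min_span = 50000, max_span = 10e6,
                         max_q = 0.05) {
  inter <- loops$chrom1 != loops$chrom2
  if (any(inter)) {
    message(sum(inter), " inter-chromosomal loop record(s) rejected")
    loops <- loops[!inter, , drop = FALSE]
  }
  if (nrow(loops) == 0) return(loops)
  if (anyNA(loops$q_value)) {
    warning(sum(is.na(loops$q_value)),
            " loop(s) without q-value treated as passing")
  }
  span <- loop_span(loops)
  q_ok <- is.na(loops$q_value) | loops$q_value < max_q
  keep <- span >= min_span & span < max_span & q_ok
  out <- loops[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Loops anchored at a genomic position
#'
#' @param chrom,pos0 the position (e.g. a risk SNP base or CTCF summit).
#' @param loops loop table (already filtered).
#' @return data.frame with `loop` (row index into `loops`) and `anchor`
#'   (1 or 2); loop interiors do not count.
#' @export
anchor_hits <- function(chrom, pos0, loops) {
  in1 <- loops$chrom1 == chrom & loops$start1 <= pos0 & pos0 < loops$end1
  in2 <- loops$chrom2 == chrom & loops$start2 <= pos0 & pos0 < loops$end2
  data.frame(loop = c(which(in1), which(in2)),
             anchor = c(rep(1L, sum(in1)), rep(2L, sum(in2))))
}

#' Cross-dataset support for a loop
#'
#' A dataset supports the query loop iff it contains a loop whose two anchor
#' midpoints each lie within `slack` bp of the query's respective anchor
#' midpoints (default one 10-kb matrix bin). The query's own dataset always
#' counts.
#'
#' @param query_loop single-row loop table.
#' @param all_datasets named list of loop tables, one per interaction
#'   dataset.
#' @param slack matching tolerance in bp; support is monotone
#'   non-decreasing in `slack`.
#' @return list with `support` (integer) and `supporting_datasets`.
#' @export
cross_dataset_support <- function(query_loop, all_datasets, slack = 10000) {
  if (slack < 0) stop("slack must be >= 0")
  qm1 <- floor((query_loop$start1 + query_loop$end1) / 2)
  qm2 <- floor((query_loop$start2 + query_loop$end2) / 2)
  supp <- vapply(all_datasets, function(lp) {
    if (nrow(lp) == 0) return(FALSE)
    m1 <- floor((lp$start1 + lp$end1) / 2)
    m2 <- floor((lp$start2 + lp$end2) / 2)
    any(lp$chrom1 == query_loop$chrom1 & lp$chrom2 == query_loop$chrom2 &
          abs(m1 - qm1) <= slack & abs(m2 - qm2) <= slack)
  }, logical(1))
  datasets <- union(names(all_datasets)[supp],
                    stats::na.omit(query_loop$dataset))
  list(support = length(datasets), supporting_datasets = sort(datasets))
}

CONVERGENCE_CLASSES <- c("convergent", "tandem", "divergent", "ambiguous",
                         "no_motif")

#' Classify CTCF motif orientation at loop anchors
#'
#' Per anchor, the highest-scoring overlapping motif is selected; the strand
#' pair then maps to `(+,-)` convergent (motifs pointing toward each other,
#' the loop-extrusion configuration), `(+,+)`/`(-,-)` tandem, `(-,+)`
#' divergent. An anchor with no overlapping motif gives `no_motif`; an
#' anchor whose top score is shared by motifs on both strands gives
#' `ambiguous`.
#'
#' @param loop single-row canonical loop table.
#' @param motifs stranded motif table (BED6 schema with `score`, `strand`).
#' @return one of `"convergent"`, `"tandem"`, `"divergent"`, `"ambiguous"`,
#'   `"no_motif"`.
#' @export
classify_convergence <- function(loop, motifs) {
  top_strand <- function(chrom, start, end) {
    hit <- motifs$chrom == chrom & motifs$start < end & motifs$end > start
    if (!any(hit)) return(NA_character_)
    m <- motifs[hit, , drop = FALSE]
    top <- m[m$score == max(m$score), , drop = FALSE]
    st <- unique(top$strand)
    if (length(st) > 1) "ambiguous" else st
  }
  s1 <- top_strand(loop$chrom1, loop$start1, loop$end1)
  s2 <- top_strand(loop$chrom2, loop$start2, loop$end2)
  if (is.na(s1) || is.na(s2)) return("no_motif")
  if (s1 == "ambiguous" || s2 == "ambiguous") return("ambiguous")
  if (s1 == "+" && s2 == "-") return("convergent")
  if (s1 == "-" && s2 == "+") return("divergent")
  "tandem"
}

#' Assemble risk loops anchored at a risk site
#'
#' For every filtered loop (pooled over interaction datasets) with an anchor
#' containing the site, computes cross-dataset support, motif convergence
#' and span, and flags high-confidence risk loops (support >= `min_support`
#' datasets). Loops duplicated across datasets (same anchors within `slack`)
#' are collapsed to one record keeping the lowest q-value.
#'
#' @param site list or data.frame with `chrom`, `pos0`.
#' @param loops_by_dataset named list of filtered loop tables.
#' @param motifs stranded motif table.
#' @param slack cross-dataset anchor matching tolerance, bp.
#' @param min_support datasets required for the high-confidence flag.
#' @return data.frame of risk loops: anchors, `dataset`, `q_value`,
#'   `anchor` (which anchor holds the site), `span_bp`, `support`,
#'   `supporting_datasets`, `convergence`, `high_confidence`.
#' @export
build_risk_loops <- function(site, loops_by_dataset, motifs, slack = 10000,
                             min_support = 2) {
  anchored <- do.call(rbind, lapply(names(loops_by_dataset), function(ds) {
    lp <- loops_by_dataset[[ds]]
    hits <- anchor_hits(site$chrom, site$pos0, lp)
    if (nrow(hits) == 0) return(NULL)
    out <- lp[hits$loop, , drop = FALSE]
    out$anchor <- hits$anchor
    out
  }))
  if (is.null(anchored) || nrow(anchored) == 0) {
    out <- empty_loops()
    out$anchor <- integer(0); out$span_bp <- numeric(0)
    out$support <- integer(0); out$supporting_datasets <- character(0)
    out$convergence <- character(0); out$high_confidence <- logical(0)
    return(out)
  }
  anchored$span_bp <- loop_span(anchored)
  # collapse near-identical loops found in several datasets
  key <- paste(anchored$chrom1,
               round(floor((anchored$start1 + anchored$end1) / 2) / slack),
               round(floor((anchored$start2 + anchored$end2) / 2) / slack))
  ord <- order(key, anchored$q_value)
  anchored <- anchored[ord, , drop = FALSE]
  anchored <- anchored[!duplicated(key[ord]), , drop = FALSE]
  sup <- lapply(seq_len(nrow(anchored)), function(i) {
    cross_dataset_support(anchored[i, ], loops_by_dataset, slack = slack)
  })
  anchored$support <- vapply(sup, `[[`, integer(1), "support")
  anchored$supporting_datasets <- vapply(sup, function(x)
    paste(x$supporting_datasets, collapse = ","), "")
  anchored$convergence <- vapply(seq_len(nrow(anchored)), function(i)
    classify_convergence(anchored[i, ], motifs), "")
  anchored$high_confidence <- anchored$support >= min_support
  anchored <- anchored[order(anchored$span_bp), , drop = FALSE]
  rownames(anchored) <- NULL
  anchored
}
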