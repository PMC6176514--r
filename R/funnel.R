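# The SNP funnel: fine-mapped SNPs -> open chromatin -> mark evidence ->
# loop anchors. Stages are nested: mark evidence is only recorded for SNPs
# inside a DHS, mirroring the rationale that open chromatin localises the
# functional base of a broad ChIP-seq peak.

#' Annotate fine-mapped SNPs with regulatory evidence
#'
#' Each SNP is a 1-bp interval `[pos0, pos0 + 1)`. The SNP base is tested
#' against (a) the open-chromatin (DHS) catalog, (b) every H3K27Ac HC peak
#' set (full peak intervals) and (c) every CTCF HC set as +/- `ctcf_flank`
#' windows around peak summits (peak midpoint when the summit is absent).
#' The H3K27Ac / CTCF asymmetry is deliberate: acetylation evidence is the
#' peak body, CTCF evidence is proximity to the occupancy summit. Mark
#' evidence is zeroed for SNPs outside any DHS (funnel nesting).
#'
#' @param snps data.frame with `rsid`, `chrom`, `pos0`; rsids must be unique.
#' @param dhs interval table of open-chromatin regions.
#' @param k27ac_sets,ctcf_sets lists of `hc_peak_set` objects (the dataset
#'   rosters).
#' @param ctcf_flank flank in bp around CTCF summits (default 1000).
#' @param genes optional `gene_models`; when supplied every SNP gets a
#'   genomic-context call.
#' @return object of class `annotated_snps`: the SNP table with `in_dhs`,
#'   `context`, `context_gene`, plus logical hit matrices `k27ac_hits` and
#'   `ctcf_hits` (SNP x dataset) and a `loop_hits` slot filled by
#'   [annotate_loop_hits()].
#' @export
annotate_snps <- function(snps, dhs, k27ac_sets, ctcf_sets,
                          ctcf_flank = 1000, genes = NULL) {
  if (anyDuplicated(snps$rsid)) {
    stop("duplicate rsid in SNP table: ",
         snps$rsid[duplicated(snps$rsid)][1])
  }
  if (ctcf_flank <= 0) stop("ctcf_flank must be > 0")
  n <- nrow(snps)
  k27_roster <- vapply(k27ac_sets, `[[`, "", "dataset")
  ctcf_roster <- vapply(ctcf_sets, `[[`, "", "dataset")
  if (length(k27_roster) == 0 && length(ctcf_roster) == 0) {
    stop("at least one HC peak set roster must be non-empty")
  }
  snp_iv <- if (n > 0) genomic_intervals(snps$chrom, snps$pos0, snps$pos0 + 1)
            else genomic_intervals("x", 0, 1)[0, ]

  hit_any <- function(ref) {
    if (n == 0 || nrow(ref) == 0) return(rep(FALSE, n))
    h <- find_hits(snp_iv, ref)
    out <- rep(FALSE, n)
    out[unique(S4Vectors::queryHits(h))] <- TRUE
    out
  }
  in_dhs <- hit_any(dhs)

  k27_hits <- matrix(FALSE, n, length(k27_roster),
                     dimnames = list(snps$rsid, k27_roster))
  for (j in seq_along(k27ac_sets)) {
    k27_hits[, j] <- hit_any(k27ac_sets[[j]]$peaks) & in_dhs
  }
  ctcf_hits <- matrix(FALSE, n, length(ctcf_roster),
                      dimnames = list(snps$rsid, ctcf_roster))
  for (j in seq_along(ctcf_sets)) {
    pk <- ctcf_sets[[j]]$peaks
    win <- if (nrow(pk) > 0) {
      window_around(pk$chrom, peak_summits(pk), ctcf_flank)
    } else pk[0, c("chrom", "start", "end")]
    ctcf_hits[, j] <- hit_any(win) & in_dhs
  }

  ann <- snps
  ann$in_dhs <- in_dhs
  if (!is.null(genes)) {
    ctx <- classify_context(snp_iv, genes)
    ann$context <- as.character(ctx$category)
    ann$context_gene <- ctx$gene_id
  } else {
    ann$context <- rep(NA_character_, n)
    ann$context_gene <- rep(NA_character_, n)
  }
  structure(list(snps = ann, k27ac_hits = k27_hits, ctcf_hits = ctcf_hits,
                 loop_hits = NULL,
                 rosters = list(k27ac = k27_roster, ctcf = ctcf_roster,
                                loops = character(0))),
            class = "annotated_snps")
}

#' @export
print.annotated_snps <- function(x, ...) {
  fc <- funnel_counts(x)
  cat(sprintf(paste0("annotated_snps: %d SNPs | %d in DHS | %d +H3K27Ac | ",
                     "%d +CTCF\n"),
              fc$n_input, fc$n_dhs, fc$n_dhs_k27ac, fc$n_dhs_ctcf))
  invisible(x)
}

#' Record loop-anchor membership per interaction dataset
#'
#' Tests every SNP base against the anchors of the (already filtered) loops
#' of each interaction dataset and stores a logical SNP x dataset matrix.
#'
#' @param annotated an `annotated_snps` object.
#' @param loops_by_dataset named list of filtered loop tables, one per
#'   interaction dataset.
#' @return the updated `annotated_snps`.
#' @export
annotate_loop_hits <- function(annotated, loops_by_dataset) {
  snps <- annotated$snps
  n <- nrow(snps)
  roster <- names(loops_by_dataset)
  if (is.null(roster) || any(!nzchar(roster))) {
    stop("loops_by_dataset must be a named list")
  }
  snp_iv <- if (n > 0) genomic_intervals(snps$chrom, snps$pos0, snps$pos0 + 1)
            else NULL
  hits <- matrix(FALSE, n, length(roster),
                 dimnames = list(snps$rsid, roster))
  for (j in seq_along(roster)) {
    lp <- loops_by_dataset[[j]]
    if (n == 0 || nrow(lp) == 0) next
    anchors <- rbind(
      genomic_intervals(lp$chrom1, lp$start1, lp$end1),
      genomic_intervals(lp$chrom2, lp$start2, lp$end2))
    h <- find_hits(snp_iv, anchors)
    hits[unique(S4Vectors::queryHits(h)), j] <- TRUE
  }
  annotated$loop_hits <- hits
  annotated$rosters$loops <- roster
  annotated
}

#' Funnel stage counts
#'
#' A SNP counts once per stage regardless of how many datasets hit it. Loop
#' stages are `NA` when [annotate_loop_hits()] has not been applied.
#'
#' @param annotated an `annotated_snps` object.
#' @return data.frame with one row: `n_input`, `n_dhs`, `n_dhs_k27ac`,
#'   `n_dhs_ctcf`, `n_dhs_k27ac_loop`, `n_dhs_ctcf_loop`.
#' @export
funnel_counts <- function(annotated) {
  s <- annotated$snps
  any_row <- function(m) if (ncol(m) == 0) rep(FALSE, nrow(s)) else
    rowSums(m) > 0
  k27 <- any_row(annotated$k27ac_hits)
  ctcf <- any_row(annotated$ctcf_hits)
  if (is.null(annotated$loop_hits)) {
    lk <- NA_integer_
    lc <- NA_integer_
  } else {
    loop <- any_row(annotated$loop_hits)
    lk <- sum(k27 & loop)
    lc <- sum(ctcf & loop)
  }
  out <- data.frame(n_input = nrow(s), n_dhs = sum(s$in_dhs),
                    n_dhs_k27ac = sum(k27), n_dhs_ctcf = sum(ctcf),
                    n_dhs_k27ac_loop = lk, n_dhs_ctcf_loop = lc)
  stopifnot(out$n_input >= out$n_dhs,
            out$n_dhs >= out$n_dhs_k27ac, out$n_dhs >= out$n_dhs_ctcf,
            is.na(lk) || out$n_dhs_k27ac >= lk,
            is.na(lc) || out$n_dhs_ctcf >= lc)
  out
}

#' Per-SNP x per-dataset evidence matrix
#'
#' One row per SNP passing the mark-specific stage (in a DHS and hit in >= 1
#' dataset of that mark), with its genomic context, the per-dataset hit
#' vector for the mark and, when available, per-interaction-dataset
#' loop-anchor membership. Rows are ordered deterministically by
#' (chrom, pos, rsid).
#'
#' @param annotated an `annotated_snps` object.
#' @param mark `"k27ac"` or `"ctcf"`.
#' @return data.frame.
#' @export
evidence_matrix <- function(annotated, mark = c("k27ac", "ctcf")) {
  mark <- match.arg(mark)
  m <- if (mark == "k27ac") annotated$k27ac_hits else annotated$ctcf_hits
  s <- annotated$snps
  pass <- s$in_dhs & (if (ncol(m) == 0) FALSE else rowSums(m) > 0)
  out <- data.frame(rsid = s$rsid, chrom = s$chrom, pos0 = s$pos0,
                    context = s$context, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(m))
  if (!is.null(annotated$loop_hits)) {
    lh <- annotated$loop_hits
    colnames(lh) <- paste0("loop_", colnames(lh))
    out <- cbind(out, as.data.frame(lh))
  }
  out <- out[pass, , drop = FALSE]
  out <- out[order(out$chrom, out$pos0, out$rsid), , drop = FALSE]
  rownames(out) <- NULL
  out
}
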