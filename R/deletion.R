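# Expression consequences of an anchor deletion: per-gene fold changes in
# the +/- 1 Mb window around the deleted site and top-responder calling.
# This is the descriptive locus-level layer (fold change on
# library-size-normalised counts with a pseudocount); genome-wide
# differential-expression modelling is out of scope.

#' Deletion experiment container
#'
#' @param deletion single-row interval table (the deleted region).
#' @param control_samples,deleted_samples column names of `expression`
#'   belonging to each group; both non-empty and disjoint.
#' @param expression gene x sample matrix of non-negative values with gene
#'   ids as rownames.
#' @return object of class `deletion_experiment`.
#' @export
deletion_experiment <- function(deletion, control_samples, deleted_samples,
                                expression) {
  if (length(control_samples) == 0 || length(deleted_samples) == 0) {
    stop("both sample groups must be non-empty")
  }
  if (length(intersect(control_samples, deleted_samples)) > 0) {
    stop("control and deleted sample sets overlap")
  }
  missing <- setdiff(c(control_samples, deleted_samples),
                     colnames(expression))
  if (length(missing) > 0) {
    stop("samples absent from expression matrix: ",
         paste(missing, collapse = ", "))
  }
  if (any(expression < 0)) stop("expression values must be non-negative")
  if (deletion$end <= deletion$start) stop("deletion interval must be > 0 bp")
  structure(list(deletion = deletion, control_samples = control_samples,
                 deleted_samples = deleted_samples, expression = expression),
            class = "deletion_experiment")
}

#' Per-gene fold changes for a deletion experiment
#'
#' Samples are library-size normalised (each column scaled so all sample
#' sums equal the mean library size), then per gene
#' `fold_change = (mean(deleted) + pseudocount) / (mean(control) +
#' pseudocount)`. The pseudocount keeps unexpressed genes at fold change 1
#' and bounds fold changes away from 0/Inf. Rescaling any sample column by a
#' positive constant leaves the ratio of normalised means unchanged, so fold
#' changes are invariant up to the pseudocount (exactly so as the
#' pseudocount tends to 0; negligible at defaults for genes expressed well
#' above the pseudocount). Swapping the group labels maps every `log2fc` to
#' its negative.
#'
#' @param exp a `deletion_experiment`.
#' @param pseudocount positive constant added to both group means
#'   (default 0.5).
#' @param normalize library-size normalise before averaging (default TRUE).
#' @param genes optional character vector restricting (and checking) the
#'   genes reported; an absent gene is an error naming it.
#' @param n_perm if > 0, append a label-permutation p-value per gene: the
#'   fraction of `n_perm` random group relabellings whose |log2fc| is at
#'   least the observed one (with the +1 small-sample correction).
#' @param perm_seed seed for the permutation draw.
#' @return data.frame with `gene_id`, `mean_control`, `mean_deleted`,
#'   `fold_change`, `log2fc` (and `p_perm` when requested).
#' @export
compute_fold_changes <- function(exp, pseudocount = 0.5, normalize = TRUE,
                                 genes = NULL, n_perm = 0, perm_seed = 1) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  mat <- exp$expression
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(mat))
    if (length(missing) > 0) {
      stop("gene absent from expression matrix: ", missing[1])
    }
    mat <- mat[genes, , drop = FALSE]
  }
  cols <- c(exp$control_samples, exp$deleted_samples)
  mat <- mat[, cols, drop = FALSE]
  if (normalize) {
    libsize <- colSums(exp$expression[, cols, drop = FALSE])
    if (any(libsize == 0)) stop("sample with zero library size")
    mat <- sweep(mat, 2, mean(libsize) / libsize, `*`)
  }
  fc_for <- function(ctrl, del) {
    mc <- rowMeans(mat[, ctrl, drop = FALSE])
    md <- rowMeans(mat[, del, drop = FALSE])
    (md + pseudocount) / (mc + pseudocount)
  }
  fc <- fc_for(exp$control_samples, exp$deleted_samples)
  mc <- rowMeans(mat[, exp$control_samples, drop = FALSE])
  md <- rowMeans(mat[, exp$deleted_samples, drop = FALSE])
  out <- data.frame(gene_id = rownames(mat), mean_control = mc,
                    mean_deleted = md, fold_change = fc, log2fc = log2(fc),
                    stringsAsFactors = FALSE)
  if (n_perm > 0) {
    set.seed(perm_seed)
    n_del <- length(exp$deleted_samples)
    obs <- abs(out$log2fc)
    exceed <- rep(0L, nrow(out))
    for (p in seq_len(n_perm)) {
      del_p <- sample(cols, n_del)
      fc_p <- fc_for(setdiff(cols, del_p), del_p)
      exceed <- exceed + (abs(log2(fc_p)) >= obs)
    }
    out$p_perm <- (exceed + 1) / (n_perm + 1)
  }
  rownames(out) <- NULL
  out
}

#' Ranked deletion-effect report for the window around a site
#'
#' Restricts the fold-change table to genes whose TSS lies within
#' +/- `window` bp of the site, annotates loop membership (TSS inside the
#' full span of any risk loop), and sorts by |log2fc| descending with ties
#' broken by genomic distance to the site. The top responder is rank 1; when
#' its fold change (in either direction) is below `min_fold` the report is
#' flagged as having no responder.
#'
#' @param effects result of [compute_fold_changes()].
#' @param site list/data.frame with `chrom`, `pos0`.
#' @param genes a `gene_models` object (TSS lookup; genes missing from it
#'   are dropped with a warning).
#' @param risk_loops optional risk-loop table for `in_loop` annotation.
#' @param window flank in bp (default 1 Mb).
#' @param min_fold responder threshold on max(fold, 1/fold) (default 2).
#' @return data.frame sorted by responsiveness, with attributes
#'   `top_responder` (gene id or `NA`) and `responder_called` (logical).
#' @export
window_report <- function(effects, site, genes, risk_loops = NULL,
                          window = 1e6, min_fold = 2) {
  g <- genes$genes
  idx <- match(effects$gene_id, g$gene_id)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " gene(s) without gene model dropped")
    effects <- effects[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  effects$chrom <- g$chrom[idx]
  effects$tss_pos0 <- g$tss_pos0[idx]
  effects$distance_bp <- abs(effects$tss_pos0 - site$pos0)
  keep <- effects$chrom == site$chrom & effects$distance_bp <= window
  rep <- effects[keep, , drop = FALSE]
  rep$in_window <- rep(TRUE, nrow(rep))
  rep$in_loop <- rep(FALSE, nrow(rep))
  if (!is.null(risk_loops)) {
    for (i in seq_len(nrow(risk_loops))) {
      rep$in_loop <- rep$in_loop | (rep$chrom == risk_loops$chrom1[i] &
                                      rep$tss_pos0 >= risk_loops$start1[i] &
                                      rep$tss_pos0 < risk_loops$end2[i])
    }
  }
  if (nrow(rep) == 0) {
    warning("no genes with TSS within the window")
    attr(rep, "top_responder") <- NA_character_
    attr(rep, "responder_called") <- FALSE
    return(rep)
  }
  rep <- rep[order(-abs(rep$log2fc), rep$distance_bp, rep$gene_id), ,
             drop = FALSE]
  rep$rank <- seq_len(nrow(rep))
  rownames(rep) <- NULL
  top_fold <- max(rep$fold_change[1], 1 / rep$fold_change[1])
  attr(rep, "top_responder") <- rep$gene_id[1]
  attr(rep, "responder_called") <- top_fold >= min_fold
  rep
}
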