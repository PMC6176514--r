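# Convenience drivers that chain the module operations the way the analysis
# scripts use them.

#' Derive HC peak sets for every dataset of a mark
#'
#' Splits a concatenated replicate-tagged peak table by dataset and
#' intersects the replicate pairs.
#'
#' @param chip_peaks peak table with `mark`, `cell_line`, `replicate`
#'   columns (replicates named `"rep1"`/`"rep2"`).
#' @param mark the mark to extract.
#' @param ... passed to [derive_hc_peaks()].
#' @return named list of `hc_peak_set` objects (one per dataset).
#' @export
hc_sets_for_mark <- function(chip_peaks, mark, ...) {
  sub <- chip_peaks[chip_peaks$mark == mark, , drop = FALSE]
  datasets <- sort(unique(sub$cell_line))
  out <- lapply(datasets, function(ds) {
    d <- sub[sub$cell_line == ds, , drop = FALSE]
    derive_hc_peaks(d[d$replicate == "rep1", , drop = FALSE],
                    d[d$replicate == "rep2", , drop = FALSE],
                    mark = mark, cell_line = ds, ...)
  })
  stats::setNames(out, datasets)
}

#' Filter loops per interaction dataset
#'
#' @param loops loop table with a `dataset` column.
#' @param ... passed to [filter_loops()].
#' @return named list of filtered loop tables.
#' @export
filter_loops_by_dataset <- function(loops, ...) {
  datasets <- sort(unique(loops$dataset))
  stats::setNames(lapply(datasets, function(ds)
    filter_loops(loops[loops$dataset == ds, , drop = FALSE], ...)), datasets)
}

#' Run the full SNP funnel
#'
#' HC peak derivation for both marks, SNP annotation, loop filtering and
#' loop-anchor membership, in one call.
#'
#' @param snps,dhs,chip_peaks,loops,genes landscape-style input tables (see
#'   [simulate_landscape()] or the readers in this package).
#' @param ctcf_flank CTCF summit flank, bp.
#' @return list with `annotated` (an `annotated_snps`), `counts`
#'   (one-row [funnel_counts()] table), `k27ac_sets`, `ctcf_sets`,
#'   `loops_by_dataset`.
#' @export
run_snp_funnel <- function(snps, dhs, chip_peaks, loops, genes = NULL,
                           ctcf_flank = 1000) {
  k27ac_sets <- hc_sets_for_mark(chip_peaks, "H3K27Ac")
  ctcf_sets <- hc_sets_for_mark(chip_peaks, "CTCF")
  annotated <- annotate_snps(snps, dhs, k27ac_sets, ctcf_sets,
                             ctcf_flank = ctcf_flank, genes = genes)
  loops_by_dataset <- filter_loops_by_dataset(loops)
  annotated <- annotate_loop_hits(annotated, loops_by_dataset)
  list(annotated = annotated, counts = funnel_counts(annotated),
       k27ac_sets = k27ac_sets, ctcf_sets = ctcf_sets,
       loops_by_dataset = loops_by_dataset)
}

#' Read landscape input files back from disk
#'
#' Counterpart of [write_landscape()]: reassembles the input tables from the
#' written SNP/DHS/narrowPeak/BEDPE/motif/GTF files.
#'
#' @param dir directory written by [write_landscape()].
#' @return list with `snps`, `dhs`, `chip_peaks`, `loops`, `motifs`,
#'   `genes`.
#' @export
read_landscape_inputs <- function(dir) {
  peak_files <- list.files(file.path(dir, "peaks"), full.names = TRUE)
  chip_peaks <- do.call(rbind, lapply(peak_files, function(f) {
    parts <- strsplit(sub("\\.narrowPeak$", "", basename(f)), "_")[[1]]
    rep <- parts[length(parts)]
    mark <- parts[1]
    ds <- paste(parts[-c(1, length(parts))], collapse = "_")
    read_narrowpeak(f, mark = mark, cell_line = ds, replicate = rep)
  }))
  loop_files <- list.files(file.path(dir, "loops"), full.names = TRUE)
  loops <- do.call(rbind, lapply(loop_files, function(f)
    read_bedpe(f, dataset = sub("\\.bedpe$", "", basename(f)))))
  list(snps = read_snp_tsv(file.path(dir, "snps.tsv")),
       dhs = read_bed(file.path(dir, "dhs.bed")),
       chip_peaks = chip_peaks, loops = loops,
       motifs = read_motif_bed(file.path(dir, "ctcf_motifs.bed")),
       genes = read_gtf_genes(file.path(dir, "genes.gtf")))
}
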