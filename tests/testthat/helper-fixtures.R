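# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except files the tests themselves write to tempdir().

mk_peaks <- function(chrom, starts, ends, summit_offset = NA_real_,
                     mark = "H3K27Ac", cell_line = "cellA",
                     replicate = "rep1", score = 100) {
  n <- length(starts)
  data.frame(chrom = rep_len(chrom, n), start = starts, end = ends,
             name = sprintf("pk%03d", seq_len(n)),
             score = rep_len(score, n), strand = ".",
             signal = 10, pvalue = 8, qvalue = 5,
             summit_offset = rep_len(summit_offset, n),
             mark = mark, cell_line = cell_line, replicate = replicate,
             stringsAsFactors = FALSE)
}

mk_loop <- function(chrom, s1, e1, s2, e2, q = 0.01, dataset = "ds1",
                    name = "loop") {
  data.frame(chrom1 = chrom, start1 = s1, end1 = e1,
             chrom2 = chrom, start2 = s2, end2 = e2,
             name = name, q_value = q, dataset = dataset,
             stringsAsFactors = FALSE)
}

mk_motif <- function(chrom, start, strand, score = 10) {
  data.frame(chrom = chrom, start = start, end = start + 19,
             name = "motif", score = score, strand = strand,
             stringsAsFactors = FALSE)
}

# one + strand gene: TSS 10000, body [10000, 30000), three exons
simple_genes <- function() {
  genes <- data.frame(gene_id = "g1", gene_name = "G1", chrom = "chr1",
                      strand = "+", start = 10000, end = 30000,
                      tss_pos0 = 10000, tes_pos0 = 29999,
                      stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = "g1", chrom = "chr1",
                      start = c(10000, 18000, 28000),
                      end = c(12000, 20000, 30000), stringsAsFactors = FALSE)
  gene_models(genes, exons)
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e5,
                             max_len = 500) {
  start <- floor(runif(n, 0, max_pos))
  genomic_intervals(sample(chroms, n, replace = TRUE), start,
                    start + floor(runif(n, 1, max_len)))
}

# O(n*m) all-pairs membership oracle for filter_overlapping
brute_filter <- function(query, reference) {
  keep <- vapply(seq_len(nrow(query)), function(i) {
    any(query$chrom[i] == reference$chrom &
          query$start[i] < reference$end &
          reference$start < query$end[i])
  }, logical(1))
  out <- query[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# per-base coverage oracle for repressive_coverage
brute_coverage <- function(interior, peaks) {
  bases <- rep(FALSE, interior$end - interior$start)
  for (i in seq_len(nrow(peaks))) {
    if (peaks$chrom[i] != interior$chrom) next
    lo <- max(peaks$start[i], interior$start) - interior$start + 1
    hi <- min(peaks$end[i], interior$end) - interior$start
    if (hi >= lo) bases[lo:hi] <- TRUE
  }
  mean(bases)
}

small_config <- function(...) {
  landscape_config(n_snps = 160, n_dhs = 60, n_k27ac = 30, n_ctcf = 16,
                   n_k27ac_loop = 20, n_ctcf_loop = 10,
                   chip_datasets = c("cellA", "cellB", "cellC"),
                   interaction_datasets = c("ds1", "ds2", "ds3"),
                   background_peaks_per_dataset = 5,
                   n_background_genes = 50, ...)
}

# the full study-scale landscape is expensive enough to build once per run
.fixture_env <- new.env(parent = emptyenv())
full_landscape <- function(seed = 1) {
  key <- paste0("landscape_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- simulate_landscape(landscape_config(), seed = seed)
  }
  .fixture_env[[key]]
}
small_landscape <- function(seed = 11) {
  key <- paste0("small_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- simulate_landscape(small_config(), seed = seed)
  }
  .fixture_env[[key]]
}
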