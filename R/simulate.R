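# Fully labelled synthetic regulatory landscape. Every downstream operation
# (HC peak derivation, the SNP funnel, loop filtering/support/convergence,
# desert detection, adoption ranking, deletion fold changes) has planted
# ground truth here, standing in for the study-scale genomic data the
# pipeline was designed for.
#
# Layout (deterministic skeleton, seeded jitter on top):
#   chr1 [0, 6.02 Mb)      anchor grid: 10-kb cells; even cells hold loop
#                          anchor1 bins (one loop-anchored SNP each), odd
#                          cells receive anchor2 bins; one oriented CTCF
#                          motif per used cell so convergence labels are
#                          unambiguous by construction.
#   chr1 ~[3.0, 13.1 Mb)   two whole-chromosome loops exercising the 10-Mb
#                          span ceiling (one just under, one exactly at it).
#   chr1 [6.2, 8.1 Mb)     the deletion locus: a risk CTCF anchor bin whose
#                          SNP anchors a 300-kb and a 715-kb loop (planted in
#                          all interaction datasets, convergent motifs),
#                          H3K27Ac-devoid interiors tiled by H3K27me3, a
#                          caged gene just inside the desert, and the nearest
#                          outside H3K27Ac enhancer ~65 kb from the site
#                          carrying risk SNPs.
#   chr2 [0, 8.6 Mb)       4-kb slots for non-loop SNPs (DHS/H3K27Ac/CTCF
#                          evidence planted per stratum).
#   chr2 [8.6, 9.4 Mb)     background replicate peak pairs with controlled
#                          reproducibility (irreproducible peaks >= 10 kb
#                          from any partner peak by the 20-kb spacing).
#   chr2 [9.4, 10 Mb)      loops straddling the 50-kb span floor and the
#                          0.05 q-value threshold.

GRID_CELL <- 10e3
SNP_SLOT <- 4e3
SNP_REGION_END <- 8.6e6
BG_REGION <- c(8.6e6, 9.4e6)
BG_SPACING <- 20e3
LOCUS_ANCHOR_START <- 7.0e6

#' Configuration for the synthetic landscape
#'
#' Defaults are the study conditions: 2,181 fine-mapped SNPs of which 443
#' fall in open chromatin, 222 additionally in H3K27Ac HC peaks (203 of
#' those in loop anchors) and 93 in CTCF summit windows (85 in loop
#' anchors); 9 cell-line/condition ChIP datasets per mark, each in
#' duplicate; 5 chromatin-interaction datasets; risk-locus loop spans of
#' 300 kb and 715 kb with the adoption enhancer ~65 kb outside; deletion
#' effects of 100 / 2 / 7 / 1 fold for the four CRISPR scenarios with
#' negative-binomial dispersion 0.1.
#'
#' @param n_snps,n_dhs,n_k27ac,n_ctcf,n_k27ac_loop,n_ctcf_loop funnel
#'   stratum sizes (nested).
#' @param chip_datasets per-mark dataset roster (cell line / condition).
#' @param interaction_datasets chromatin-interaction dataset roster.
#' @param background_peaks_per_dataset background replicate-pair peaks per
#'   dataset per mark.
#' @param background_reproducibility fraction of background peaks present in
#'   both replicates.
#' @param risk_loop_spans spans (bp) of the two risk-locus loops.
#' @param enhancer_offset distance (bp) from the risk site to the adoption
#'   enhancer centre.
#' @param deletion_width width (bp) of the risk-anchor deletion.
#' @param nb_dispersion negative-binomial dispersion of expression counts.
#' @param caged_baseline_mean baseline mean count of the caged gene.
#' @param scenario_effects named true fold effects on the caged gene for the
#'   four deletion scenarios.
#' @return a validated config list.
#' @export
landscape_config <- function(n_snps = 2181, n_dhs = 443, n_k27ac = 222,
                             n_ctcf = 93, n_k27ac_loop = 203,
                             n_ctcf_loop = 85,
                             chip_datasets = c("PrEC", "RWPE1", "RWPE2",
                                               "22Rv1", "22Rv1_DHT", "C42B",
                                               "LNCaP", "LNCaP_DHT", "VCaP"),
                             interaction_datasets = c("HiC_RWPE1",
                                                      "HiC_22Rv1",
                                                      "HiC_C42B",
                                                      "HiC_GM12878",
                                                      "HiChIP_GM12878"),
                             background_peaks_per_dataset = 15,
                             background_reproducibility = 0.8,
                             risk_loop_spans = c(300e3, 715e3),
                             enhancer_offset = 65e3,
                             deletion_width = 1607,
                             nb_dispersion = 0.1,
                             caged_baseline_mean = 40,
                             n_background_genes = 300,
                             scenario_effects = c(risk_anchor_deleted = 100,
                                                  partner_anchor_deleted = 2,
                                                  double_partner_deleted = 7,
                                                  control = 1)) {
  cfg <- list(n_snps = n_snps, n_dhs = n_dhs, n_k27ac = n_k27ac,
              n_ctcf = n_ctcf, n_k27ac_loop = n_k27ac_loop,
              n_ctcf_loop = n_ctcf_loop, chip_datasets = chip_datasets,
              interaction_datasets = interaction_datasets,
              background_peaks_per_dataset = background_peaks_per_dataset,
              background_reproducibility = background_reproducibility,
              risk_loop_spans = sort(risk_loop_spans),
              enhancer_offset = enhancer_offset,
              deletion_width = deletion_width,
              nb_dispersion = nb_dispersion,
              caged_baseline_mean = caged_baseline_mean,
              n_background_genes = n_background_genes,
              scenario_effects = scenario_effects,
              genome = c(chr1 = 14e6, chr2 = 10e6))
  if (n_ctcf_loop < 1) stop("infeasible config: need >= 1 CTCF loop SNP (the risk locus)")
  if (n_k27ac_loop + n_ctcf_loop - 1 > 300) {
    stop("infeasible config: anchor grid holds at most 300 loops")
  }
  if (n_k27ac < n_k27ac_loop || n_ctcf < n_ctcf_loop) {
    stop("infeasible config: loop strata exceed mark strata")
  }
  if (n_dhs < n_k27ac + n_ctcf) {
    stop("infeasible config: mark strata exceed the DHS stratum")
  }
  if (n_snps < n_dhs) stop("infeasible config: DHS stratum exceeds input")
  n_chr2 <- n_snps - n_k27ac_loop - n_ctcf_loop
  if (n_chr2 * SNP_SLOT > SNP_REGION_END) {
    stop("infeasible config: too many non-loop SNPs for the chr2 grid")
  }
  if (background_peaks_per_dataset > 39) {
    stop("infeasible config: at most 39 background peaks per dataset")
  }
  if (max(cfg$risk_loop_spans) > 1.05e6) {
    stop("infeasible config: risk loop would leave the deletion locus")
  }
  if (min(cfg$risk_loop_spans) <= 2 * GRID_CELL) {
    stop("infeasible config: desert interior longer than its loop is impossible")
  }
  cfg
}

runif_int <- function(n, lo, hi) floor(stats::runif(n, lo, hi + 1))

#' Simulate the labelled regulatory landscape
#'
#' Regenerating with the same seed is bit-identical. See the package
#' vignette for what the generator emulates and what it deliberately leaves
#' out.
#'
#' @param config from [landscape_config()].
#' @param seed integer RNG seed.
#' @return object of class `landscape`: input tables (`snps`, `dhs`,
#'   `chip_peaks`, `loops`, `motifs`, `genes`) plus planted truth
#'   (`snps$stratum`, `chip_peaks$reproducible`, `loops$convergence`,
#'   `loops$support`, the `locus` description and expression baselines).
#' @export
simulate_landscape <- function(config = landscape_config(), seed = 1) {
  set.seed(seed)
  cfg <- config
  n_grid <- cfg$n_k27ac_loop + (cfg$n_ctcf_loop - 1)

  ## ---- anchor-grid loops (one loop-anchored SNP each) ----
  i <- seq_len(n_grid)
  a1_start <- (2 * (i - 1)) * GRID_CELL
  span <- (5 + 2 * ((i - 1) %% 13)) * GRID_CELL       # 50..290 kb, no
  a2_start <- a1_start + span                          # anchor2 collisions
  grid_loops <- data.frame(
    chrom1 = "chr1", start1 = a1_start, end1 = a1_start + GRID_CELL,
    chrom2 = "chr1", start2 = a2_start, end2 = a2_start + GRID_CELL,
    name = sprintf("grid_loop_%03d", i),
    q_value = round(stats::runif(n_grid, 0.001, 0.049), 5),
    dataset = NA_character_, stringsAsFactors = FALSE)
  grid_loops$support <- sample(seq_along(cfg$interaction_datasets), n_grid,
                               replace = TRUE)
  member <- lapply(grid_loops$support, function(s)
    sort(sample(cfg$interaction_datasets, s)))
  cls <- sample(c("convergent", "tandem", "divergent"), n_grid,
                replace = TRUE, prob = c(0.5, 0.3, 0.2))
  s1 <- ifelse(cls == "convergent", "+",
               ifelse(cls == "divergent", "-",
                      sample(c("+", "-"), n_grid, replace = TRUE)))
  s2 <- ifelse(cls == "convergent", "-",
               ifelse(cls == "divergent", "+", s1))
  grid_loops$convergence <- cls
  grid_loops$type <- "snp_anchor"
  motif_at <- function(cell_start, strand, score) {
    mid <- cell_start + GRID_CELL / 2
    data.frame(chrom = "chr1", start = mid - 9, end = mid + 10,
               name = "CTCF_motif", score = score, strand = strand,
               stringsAsFactors = FALSE)
  }
  motifs <- rbind(
    do.call(rbind, lapply(i, function(k)
      motif_at(a1_start[k], s1[k], round(stats::runif(1, 5, 15), 2)))),
    do.call(rbind, lapply(i, function(k)
      motif_at(a2_start[k], s2[k], round(stats::runif(1, 5, 15), 2)))))

  ## ---- deletion locus ----
  S0 <- LOCUS_ANCHOR_START
  site_pos <- S0 + GRID_CELL / 2
  spans <- cfg$risk_loop_spans
  risk_loops <- data.frame(
    chrom1 = "chr1", start1 = S0, end1 = S0 + GRID_CELL,
    chrom2 = "chr1", start2 = S0 + spans,
    end2 = S0 + spans + GRID_CELL,
    name = sprintf("risk_loop_%d", seq_along(spans)),
    q_value = round(stats::runif(length(spans), 0.001, 0.02), 5),
    dataset = NA_character_, stringsAsFactors = FALSE)
  risk_loops$support <- length(cfg$interaction_datasets)
  risk_loops$convergence <- "convergent"
  risk_loops$type <- "risk"
  motifs <- rbind(motifs,
    data.frame(chrom = "chr1", start = site_pos - 9, end = site_pos + 10,
               name = "CTCF_motif", score = 18, strand = "+",
               stringsAsFactors = FALSE),
    data.frame(chrom = "chr1", start = S0 + 2000, end = S0 + 2019,
               name = "CTCF_motif", score = 6, strand = "-",
               stringsAsFactors = FALSE),   # weaker opposing motif in the
    do.call(rbind, lapply(spans, function(sp) {  # risk anchor
      mid <- S0 + sp + GRID_CELL / 2
      data.frame(chrom = "chr1", start = mid - 9, end = mid + 10,
                 name = "CTCF_motif", score = 16, strand = "-",
                 stringsAsFactors = FALSE)
    })))

  ## ---- whole-chromosome span-ceiling loops (SNP-free anchors apart from
  ##      the grid cell the lower anchor happens to share) ----
  mega_loops <- data.frame(
    chrom1 = "chr1", start1 = c(3.0e6, 3.02e6), end1 = c(3.01e6, 3.03e6),
    chrom2 = "chr1", start2 = c(3.0e6, 3.02e6) + c(9.98e6, 10e6),
    end2 = c(3.01e6, 3.03e6) + c(9.98e6, 10e6),
    name = c("mega_loop_kept", "mega_loop_span_10Mb"),
    q_value = c(0.01, 0.01), dataset = NA_character_,
    support = 1L, convergence = "no_motif", type = "mega",
    stringsAsFactors = FALSE)

  ## ---- boundary loops on chr2 (span floor and q threshold) ----
  b0 <- 9.4e6
  boundary_loops <- data.frame(
    chrom1 = "chr2",
    start1 = b0 + c(0, 1, 2, 3, 4, 5) * 15e3,
    chrom2 = "chr2", name = c("b_span_40k", "b_span_49999", "b_span_50k",
                              "b_span_220k", "b_q_0.05", "b_q_0.06"),
    q_value = c(0.01, 0.01, 0.01, 0.049, 0.05, 0.06),
    dataset = NA_character_, support = 1L, convergence = "no_motif",
    type = "boundary", stringsAsFactors = FALSE)
  bspan <- c(40e3, 49999, 50e3, 220e3, 60e3, 60e3)
  boundary_loops$end1 <- boundary_loops$start1 + GRID_CELL
  boundary_loops$start2 <- boundary_loops$start1 + bspan
  boundary_loops$end2 <- boundary_loops$start2 + GRID_CELL
  boundary_loops <- boundary_loops[, names(mega_loops)]
  boundary_loops$keep_expected <- c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE)
  mega_loops$keep_expected <- c(TRUE, FALSE)
  grid_loops$keep_expected <- TRUE
  risk_loops$keep_expected <- TRUE

  ## assign loops to interaction datasets
  expand_loops <- function(df, members) {
    do.call(rbind, lapply(seq_len(nrow(df)), function(k) {
      out <- df[rep(k, length(members[[k]])), , drop = FALSE]
      out$dataset <- members[[k]]
      out
    }))
  }
  all_ds <- cfg$interaction_datasets
  loops <- rbind(
    expand_loops(grid_loops, member),
    expand_loops(risk_loops, rep(list(all_ds), nrow(risk_loops))),
    expand_loops(mega_loops, rep(list(all_ds[1]), nrow(mega_loops))),
    expand_loops(boundary_loops, rep(list(all_ds[1]), nrow(boundary_loops))))
  rownames(loops) <- NULL

  ## ---- SNP strata and positions ----
  n_enh <- min(2, cfg$n_k27ac - cfg$n_k27ac_loop)
  strata <- c(rep("dhs_k27ac_loop", cfg$n_k27ac_loop),
              rep("dhs_ctcf_loop", cfg$n_ctcf_loop - 1))
  grid_strata <- sample(strata)                       # shuffle over cells
  n_k27_rest <- cfg$n_k27ac - cfg$n_k27ac_loop - n_enh
  n_ctcf_rest <- cfg$n_ctcf - cfg$n_ctcf_loop
  n_dhs_only <- cfg$n_dhs - cfg$n_k27ac - cfg$n_ctcf
  n_none <- cfg$n_snps - cfg$n_dhs
  chr2_strata <- sample(c(rep("dhs_k27ac", n_k27_rest),
                          rep("dhs_ctcf", n_ctcf_rest),
                          rep("dhs", n_dhs_only),
                          rep("none", n_none)))
  snps <- rbind(
    data.frame(chrom = "chr1",
               pos0 = a1_start + GRID_CELL / 2 + runif_int(n_grid, -500, 500),
               stratum = grid_strata, stringsAsFactors = FALSE),
    data.frame(chrom = "chr1", pos0 = site_pos, stratum = "dhs_ctcf_loop",
               stringsAsFactors = FALSE),
    data.frame(chrom = "chr1",
               pos0 = site_pos - cfg$enhancer_offset +
                 c(-500, 500)[seq_len(n_enh)],
               stratum = rep("dhs_k27ac", n_enh), stringsAsFactors = FALSE),
    data.frame(chrom = "chr2",
               pos0 = (seq_len(length(chr2_strata)) - 1) * SNP_SLOT +
                 SNP_SLOT / 2 + runif_int(length(chr2_strata), -500, 500),
               stratum = chr2_strata, stringsAsFactors = FALSE))
  snps$rsid <- sprintf("rs%07d", sample.int(9999999, nrow(snps)))
  snps <- snps[sample.int(nrow(snps)), c("rsid", "chrom", "pos0", "stratum")]
  rownames(snps) <- NULL
  snps$in_anchor_of <- NA_character_

  ## ---- evidence tracks per SNP ----
  has_dhs <- snps$stratum != "none"
  dj <- runif_int(sum(has_dhs), 0, 60)
  dhs <- genomic_intervals(snps$chrom[has_dhs],
                           snps$pos0[has_dhs] - 100 - dj,
                           snps$pos0[has_dhs] + 101 + dj)
  dhs <- sort_intervals(dhs)

  peak_rows <- list()
  add_peak <- function(chrom, start, end, summit_abs, mark, dataset) {
    k <- length(peak_rows) + 1
    js <- round(stats::rnorm(1, 0, 50)); je <- round(stats::rnorm(1, 0, 50))
    jsum <- round(stats::rnorm(1, 0, 20))
    s2 <- min(max(start + js, start - 150), summit_abs - 50)
    e2 <- max(min(end + je, end + 150), summit_abs + 50)
    sum2 <- min(max(summit_abs + jsum, s2 + 1), e2 - 1)
    peak_rows[[k]] <<- data.frame(
      chrom = chrom, start = c(start, s2), end = c(end, e2),
      name = sprintf("%s_%s_pk%05d_rep%d", mark, dataset, k, 1:2),
      score = round(stats::runif(1, 100, 1000)), strand = ".",
      signal = round(stats::runif(1, 2, 50), 3), pvalue = 8, qvalue = 5,
      summit_offset = c(summit_abs - start, sum2 - s2),
      mark = mark, cell_line = dataset, replicate = c("rep1", "rep2"),
      reproducible = TRUE, stringsAsFactors = FALSE)
  }

  k27_datasets_of <- vector("list", nrow(snps))
  ctcf_datasets_of <- vector("list", nrow(snps))
  enh_center <- site_pos - cfg$enhancer_offset
  enh_snp <- snps$chrom == "chr1" & abs(snps$pos0 - enh_center) < 1500 &
    snps$stratum == "dhs_k27ac"
  # the adoption enhancer itself: one peak shared by the risk SNPs it holds
  enh_sets <- sort(sample(cfg$chip_datasets, min(4, length(cfg$chip_datasets))))
  for (ds in enh_sets) {
    add_peak("chr1", enh_center - 1000, enh_center + 1000, enh_center,
             "H3K27Ac", ds)
  }
  k27_datasets_of[enh_snp] <- rep(list(enh_sets), sum(enh_snp))

  for (r in which(!enh_snp)) {
    st <- snps$stratum[r]
    if (st %in% c("dhs_k27ac", "dhs_k27ac_loop")) {
      sets <- sort(sample(cfg$chip_datasets,
                          min(runif_int(1, 1, 3), length(cfg$chip_datasets))))
      for (ds in sets) {
        w1 <- runif_int(1, 300, 900); w2 <- runif_int(1, 300, 900)
        add_peak(snps$chrom[r], snps$pos0[r] - w1, snps$pos0[r] + w2,
                 snps$pos0[r], "H3K27Ac", ds)
      }
      k27_datasets_of[[r]] <- sets
    } else if (st %in% c("dhs_ctcf", "dhs_ctcf_loop")) {
      sets <- sort(sample(cfg$chip_datasets,
                          min(runif_int(1, 1, 3), length(cfg$chip_datasets))))
      delta <- if (snps$pos0[r] == site_pos) 0 else runif_int(1, -500, 500)
      for (ds in sets) {
        summit <- snps$pos0[r] + delta
        add_peak(snps$chrom[r], summit - 300, summit + 300, summit,
                 "CTCF", ds)
      }
      ctcf_datasets_of[[r]] <- sets
    }
  }

  # CTCF occupancy at the partner anchors of the risk loops (no SNPs there)
  for (sp in spans) {
    mid <- S0 + sp + GRID_CELL / 2
    for (ds in sample(cfg$chip_datasets, min(3, length(cfg$chip_datasets)))) {
      add_peak("chr1", mid - 250, mid + 250, mid, "CTCF", ds)
    }
  }

  ## background replicate pairs with controlled reproducibility
  for (mark in c("H3K27Ac", "CTCF")) {
    for (d in seq_along(cfg$chip_datasets)) {
      ds <- cfg$chip_datasets[d]
      for (k in seq_len(cfg$background_peaks_per_dataset)) {
        center <- BG_REGION[1] + (k - 1) * BG_SPACING + 5e3 +
          (d - 1) * 200 + (mark == "CTCF") * 2500
        reproducible <- stats::runif(1) < cfg$background_reproducibility
        w <- runif_int(1, 400, 800)
        if (reproducible) {
          add_peak("chr2", center - w, center + w, center, mark, ds)
        } else {
          kk <- length(peak_rows) + 1
          peak_rows[[kk]] <- data.frame(
            chrom = "chr2", start = center - w, end = center + w,
            name = sprintf("%s_%s_pk%05d_rep1", mark, ds, kk),
            score = round(stats::runif(1, 100, 1000)), strand = ".",
            signal = round(stats::runif(1, 2, 50), 3), pvalue = 8, qvalue = 5,
            summit_offset = w, mark = mark, cell_line = ds,
            replicate = "rep1", reproducible = FALSE,
            stringsAsFactors = FALSE)
        }
      }
    }
  }

  ## H3K27me3 tiling of the larger risk-loop interior (20-kb peaks, 1-kb
  ## gaps -> coverage ~ 0.95)
  interior <- c(S0 + GRID_CELL, S0 + max(spans))
  tile_starts <- seq(interior[1], interior[2] - 20e3, by = 21e3)
  for (ts in tile_starts) {
    add_peak("chr1", ts, min(ts + 20e3, interior[2]), ts + 10e3,
             "H3K27me3", "22Rv1")
  }
  chip_peaks <- do.call(rbind, peak_rows)
  rownames(chip_peaks) <- NULL

  ## ---- gene models ----
  gene_at <- function(id, name, chrom, tss, strand, len = 20e3) {
    gstart <- if (strand == "+") tss else tss - len + 1
    gend <- gstart + len
    data.frame(gene_id = id, gene_name = name, chrom = chrom,
               strand = strand, start = gstart, end = gend,
               stringsAsFactors = FALSE)
  }
  gtab <- rbind(
    gene_at("gene_caged", "CAGED1", "chr1", S0 + 12e3, "+"),
    gene_at("gene_loopb1", "LOOPB1", "chr1", S0 + 400e3, "+"),
    gene_at("gene_loopb2", "LOOPB2", "chr1", S0 + 550e3, "-"),
    gene_at("gene_up1", "NBRU1", "chr1", S0 - 800e3, "+"),
    gene_at("gene_up2", "NBRU2", "chr1", S0 - 650e3, "-"),
    gene_at("gene_up3", "NBRU3", "chr1", S0 - 500e3, "+"),
    gene_at("gene_up4", "NBRU4", "chr1", S0 - 350e3, "+"),
    gene_at("gene_up5", "NBRU5", "chr1", S0 - 200e3, "-"),
    gene_at("gene_dn1", "NBRD1", "chr1", S0 + 800e3, "+"),
    gene_at("gene_dn2", "NBRD2", "chr1", S0 + 900e3, "-"),
    gene_at("gene_far1", "FARUP1", "chr1", S0 - 1.5e6, "+"),
    gene_at("gene_far2", "FARDN1", "chr1", S0 + 1.5e6, "-"),
    gene_at("gene_c2a", "CH2A", "chr2", 9.02e6, "+"),
    gene_at("gene_c2b", "CH2B", "chr2", 9.12e6, "-"),
    gene_at("gene_c2c", "CH2C", "chr2", 9.22e6, "+"))
  # transcriptome backbone on chr2: keeps the library size large relative to
  # any single-gene perturbation, as in real RNA-seq
  n_bg <- cfg$n_background_genes
  if (n_bg > 0) {
    bg_tss <- (seq_len(n_bg) - 1) * 33e3 + 11e3
    bg <- do.call(rbind, lapply(seq_len(n_bg), function(k)
      gene_at(sprintf("gene_bg%03d", k), sprintf("BG%03d", k), "chr2",
              bg_tss[k], c("+", "-")[1 + k %% 2], len = 8e3)))
    gtab <- rbind(gtab, bg)
  }
  gtab$tss_pos0 <- ifelse(gtab$strand == "+", gtab$start, gtab$end - 1)
  gtab$tes_pos0 <- ifelse(gtab$strand == "+", gtab$end - 1, gtab$start)
  exons <- do.call(rbind, lapply(seq_len(nrow(gtab)), function(k) {
    g <- gtab[k, ]
    len <- g$end - g$start
    if (len >= 20e3) {
      data.frame(gene_id = g$gene_id, chrom = g$chrom,
                 start = g$start + c(0, 8e3, 16e3),
                 end = g$start + c(2e3, 10e3, 20e3),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(gene_id = g$gene_id, chrom = g$chrom,
                 start = g$start + c(0, 5e3), end = g$start + c(2e3, 8e3),
                 stringsAsFactors = FALSE)
    }
  }))
  genes <- gene_models(gtab, exons)

  ## ---- expression baselines ----
  baseline <- stats::setNames(
    round(stats::rlnorm(nrow(gtab), log(500), 0.8)), gtab$gene_id)
  baseline["gene_caged"] <- cfg$caged_baseline_mean

  del_w <- cfg$deletion_width
  locus <- list(
    site = list(chrom = "chr1", pos0 = site_pos),
    risk_anchor = c(S0, S0 + GRID_CELL),
    deletions = list(
      risk_anchor_deleted = genomic_intervals(
        "chr1", site_pos - floor(del_w / 2),
        site_pos - floor(del_w / 2) + del_w),
      partner_anchor_deleted = genomic_intervals(
        "chr1", S0 + spans[1] - 456, S0 + spans[1] + 457),
      double_partner_deleted = genomic_intervals(
        "chr1", S0 + spans[1] - 456, S0 + spans[1] + 457),
      control = genomic_intervals("chr1", 4.0e6, 4.0e6 + 100)),
    enhancer = c(enh_center - 1000, enh_center + 1000),
    enhancer_offset = cfg$enhancer_offset,
    caged_gene = "gene_caged",
    desert_interiors = lapply(spans, function(sp)
      c(S0 + GRID_CELL, S0 + sp)))

  structure(list(config = cfg, seed = seed, genome = cfg$genome, snps = snps,
                 dhs = dhs, chip_peaks = chip_peaks, loops = loops,
                 motifs = motifs, genes = genes, locus = locus,
                 expression_baseline = baseline,
                 grid_loops = grid_loops, risk_loop_truth = risk_loops),
            class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf(paste0("synthetic landscape (seed %d): %d SNPs, %d DHS, %d ",
                     "ChIP peak records, %d loop records on %d chromosomes\n"),
              x$seed, nrow(x$snps), nrow(x$dhs), nrow(x$chip_peaks),
              nrow(x$loops), length(x$genome)))
  print(table(x$snps$stratum))
  invisible(x)
}

#' Write every landscape input file
#'
#' Emits the SNP table (TSV, 1-based), the DHS catalog (BED3), one
#' narrowPeak per ChIP dataset and replicate, one BEDPE per interaction
#' dataset, the oriented motif BED6, the gene GTF, and the planted truth as
#' JSON. Output is a pure function of the landscape object, so equal seeds
#' give byte-identical trees.
#'
#' @param landscape from [simulate_landscape()].
#' @param outdir output directory (created if needed).
#' @return invisible named list of written paths.
#' @export
write_landscape <- function(landscape, outdir) {
  dir.create(file.path(outdir, "peaks"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(outdir, "loops"), showWarnings = FALSE)
  paths <- list()
  paths$snps <- file.path(outdir, "snps.tsv")
  write_snp_tsv(landscape$snps[, c("rsid", "chrom", "pos0")], paths$snps)
  paths$dhs <- file.path(outdir, "dhs.bed")
  write_bed(landscape$dhs[, c("chrom", "start", "end")], paths$dhs)
  pk <- landscape$chip_peaks
  for (mark in unique(pk$mark)) {
    for (ds in unique(pk$cell_line[pk$mark == mark])) {
      for (rep in c("rep1", "rep2")) {
        sub <- pk[pk$mark == mark & pk$cell_line == ds &
                    pk$replicate == rep, , drop = FALSE]
        f <- file.path(outdir, "peaks",
                       sprintf("%s_%s_%s.narrowPeak", mark, ds, rep))
        write_narrowpeak(sort_intervals(sub), f)
        paths[[sprintf("%s_%s_%s", mark, ds, rep)]] <- f
      }
    }
  }
  for (ds in unique(landscape$loops$dataset)) {
    sub <- landscape$loops[landscape$loops$dataset == ds, , drop = FALSE]
    f <- file.path(outdir, "loops", paste0(ds, ".bedpe"))
    write_bedpe(sub[order(sub$chrom1, sub$start1, sub$start2), ], f)
    paths[[paste0("loops_", ds)]] <- f
  }
  paths$motifs <- file.path(outdir, "ctcf_motifs.bed")
  write_bed(landscape$motifs, paths$motifs)
  paths$genes <- file.path(outdir, "genes.gtf")
  write_gtf_genes(landscape$genes, paths$genes)
  paths$truth <- file.path(outdir, "truth.json")
  truth <- list(
    seed = landscape$seed,
    strata = as.list(table(landscape$snps$stratum)),
    snp_strata = stats::setNames(landscape$snps$stratum,
                                 landscape$snps$rsid),
    reproducible_peaks = sum(landscape$chip_peaks$reproducible &
                               landscape$chip_peaks$replicate == "rep1"),
    site = landscape$locus$site,
    caged_gene = landscape$locus$caged_gene,
    scenario_effects = as.list(landscape$config$scenario_effects))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Simulate expression for a CRISPR deletion scenario
#'
#' Negative-binomial counts for every landscape gene in `n_reps` control and
#' `n_reps` deleted samples. The caged gene's mean is multiplied by the
#' scenario's true effect (defaults 100 / 2 / 7 / 1 for risk-anchor,
#' partner-anchor, double-partner and control deletions); all other genes
#' are unchanged.
#'
#' @param landscape from [simulate_landscape()].
#' @param scenario one of `"risk_anchor_deleted"`, `"partner_anchor_deleted"`,
#'   `"double_partner_deleted"`, `"control"`.
#' @param n_reps replicates per group (>= 2).
#' @param seed RNG seed.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @return a `deletion_experiment`.
#' @export
simulate_deletion_expression <- function(landscape, scenario, n_reps = 3,
                                         seed = 1,
                                         dispersion =
                                           landscape$config$nb_dispersion) {
  effects <- landscape$config$scenario_effects
  if (!scenario %in% names(effects)) {
    stop("unknown scenario '", scenario, "'; known: ",
         paste(names(effects), collapse = ", "))
  }
  if (n_reps < 2) stop("n_reps must be >= 2")
  set.seed(seed)
  mu <- landscape$expression_baseline
  mu_del <- mu
  mu_del[landscape$locus$caged_gene] <-
    mu_del[landscape$locus$caged_gene] * effects[[scenario]]
  size <- 1 / dispersion
  draw <- function(mus, n) {
    matrix(stats::rnbinom(length(mus) * n, mu = rep(mus, n), size = size),
           nrow = length(mus))
  }
  mat <- cbind(draw(mu, n_reps), draw(mu_del, n_reps))
  rownames(mat) <- names(mu)
  colnames(mat) <- c(paste0("ctrl_", seq_len(n_reps)),
                     paste0("del_", seq_len(n_reps)))
  deletion_experiment(landscape$locus$deletions[[scenario]],
                      control_samples = paste0("ctrl_", seq_len(n_reps)),
                      deleted_samples = paste0("del_", seq_len(n_reps)),
                      expression = mat)
}
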