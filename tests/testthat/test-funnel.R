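mk_funnel_inputs <- function() {
  # three SNPs: one fully supported, one DHS-only, one outside DHS but
  # inside an H3K27Ac peak (must stay negative: stages are nested)
  snps <- data.frame(rsid = c("rs1", "rs2", "rs3"), chrom = "chr1",
                     pos0 = c(10000, 20000, 30000), stringsAsFactors = FALSE)
  dhs <- genomic_intervals("chr1", c(9900, 19900), c(10100, 20100))
  k27 <- list(
    hc_peak_set(mk_peaks("chr1", c(9500, 29500), c(10500, 30500)),
                "H3K27Ac", "cellA"),
    hc_peak_set(mk_peaks("chr1", 500000, 501000), "H3K27Ac", "cellB"))
  ctcf <- list(
    hc_peak_set(mk_peaks("chr1", 9800, 10400, summit_offset = 300),
                "CTCF", "cellA"))
  list(snps = snps, dhs = dhs, k27 = k27, ctcf = ctcf)
}

test_that("evidence is nested inside the DHS stage", {
  x <- mk_funnel_inputs()
  ann <- annotate_snps(x$snps, x$dhs, x$k27, x$ctcf)
  expect_equal(ann$snps$in_dhs, c(TRUE, TRUE, FALSE))
  expect_equal(unname(ann$k27ac_hits[, "cellA"]), c(TRUE, FALSE, FALSE))
  expect_equal(unname(ann$k27ac_hits[, "cellB"]), c(FALSE, FALSE, FALSE))
  # rs3 sits in an H3K27Ac peak but outside any DHS: all evidence false
  expect_false(any(ann$k27ac_hits["rs3", ]))
  expect_false(any(ann$ctcf_hits["rs3", ]))
})

test_that("CTCF evidence is a +/- 1 kb window around the summit", {
  summit <- 10100  # peak start 9800 + offset 300
  snps <- data.frame(rsid = c("near", "far", "edge"), chrom = "chr1",
                     pos0 = summit + c(999, 1001, 1000),
                     stringsAsFactors = FALSE)
  dhs <- genomic_intervals("chr1", snps$pos0 - 10, snps$pos0 + 10)
  ctcf <- list(hc_peak_set(mk_peaks("chr1", 9800, 10400, summit_offset = 300),
                           "CTCF", "cellA"))
  ann <- annotate_snps(snps, dhs, list(), ctcf)
  expect_equal(unname(ann$ctcf_hits[, 1]), c(TRUE, FALSE, TRUE))
})

test_that("duplicate rsids are rejected and empty input passes through", {
  x <- mk_funnel_inputs()
  dup <- rbind(x$snps, x$snps[1, ])
  expect_error(annotate_snps(dup, x$dhs, x$k27, x$ctcf), "duplicate rsid")
  ann0 <- annotate_snps(x$snps[0, ], x$dhs, x$k27, x$ctcf)
  expect_equal(funnel_counts(ann0)$n_input, 0)
})

test_that("funnel counts match hand-planted memberships and stay monotone", {
  x <- mk_funnel_inputs()
  ann <- annotate_snps(x$snps, x$dhs, x$k27, x$ctcf)
  fc <- funnel_counts(ann)
  expect_equal(fc$n_input, 3)
  expect_equal(fc$n_dhs, 2)
  expect_equal(fc$n_dhs_k27ac, 1)
  expect_equal(fc$n_dhs_ctcf, 1)
  expect_true(is.na(fc$n_dhs_k27ac_loop))
  loops <- list(ds1 = mk_loop("chr1", 9000, 11000, 200000, 210000))
  fc2 <- funnel_counts(annotate_loop_hits(ann, loops))
  expect_equal(fc2$n_dhs_k27ac_loop, 1)
  expect_equal(fc2$n_dhs_ctcf_loop, 1)
})

test_that("all SNPs outside open chromatin give an empty funnel", {
  snps <- data.frame(rsid = paste0("rs", 1:5), chrom = "chr1",
                     pos0 = 1:5 * 1e4, stringsAsFactors = FALSE)
  ann <- annotate_snps(snps, genomic_intervals("chr2", 0, 100),
                       list(hc_peak_set(mk_peaks("chr1", 9000, 51000),
                                        "H3K27Ac", "cellA")), list())
  fc <- funnel_counts(annotate_loop_hits(ann, list(ds1 = empty_loops())))
  expect_equal(unlist(fc), c(n_input = 5, n_dhs = 0, n_dhs_k27ac = 0,
                             n_dhs_ctcf = 0, n_dhs_k27ac_loop = 0,
                             n_dhs_ctcf_loop = 0))
})

test_that("annotation is invariant to SNP input order", {
  x <- mk_funnel_inputs()
  ann <- annotate_snps(x$snps, x$dhs, x$k27, x$ctcf)
  perm <- c(3, 1, 2)
  ann_p <- annotate_snps(x$snps[perm, ], x$dhs, x$k27, x$ctcf)
  expect_equal(ann_p$snps$in_dhs, ann$snps$in_dhs[perm])
  expect_equal(ann_p$k27ac_hits[x$snps$rsid, ], ann$k27ac_hits[x$snps$rsid, ])
})

test_that("an unbounded CTCF flank captures every DHS SNP on a CTCF chromosome", {
  ls <- small_landscape()
  ctcf <- hc_sets_for_mark(ls$chip_peaks, "CTCF")
  ann <- annotate_snps(ls$snps, ls$dhs, list(), ctcf, ctcf_flank = 1e9)
  s <- ann$snps
  has_ctcf_chrom <- s$chrom %in% unique(unlist(lapply(ctcf, function(x)
    x$peaks$chrom)))
  expect_identical(unname(rowSums(ann$ctcf_hits) > 0),
                   s$in_dhs & has_ctcf_chrom)
})

test_that("the evidence matrix holds stage-passing SNPs in deterministic order", {
  x <- mk_funnel_inputs()
  ann <- annotate_loop_hits(annotate_snps(x$snps, x$dhs, x$k27, x$ctcf),
                            list(ds1 = mk_loop("chr1", 9000, 11000,
                                               200000, 210000)))
  m <- evidence_matrix(ann, "k27ac")
  expect_equal(m$rsid, "rs1")
  expect_true(m$cellA)
  expect_false(m$cellB)
  expect_true(m$loop_ds1)
  expect_equal(nrow(evidence_matrix(ann, "ctcf")), 1)
  # saturation: a SNP hit everywhere gives an all-true evidence row
  snps1 <- data.frame(rsid = "rsX", chrom = "chr1", pos0 = 10000,
                      stringsAsFactors = FALSE)
  k27_all <- list(hc_peak_set(mk_peaks("chr1", 9000, 11000), "H3K27Ac", "A"),
                  hc_peak_set(mk_peaks("chr1", 9500, 10500), "H3K27Ac", "B"))
  annX <- annotate_snps(snps1, genomic_intervals("chr1", 9990, 10010),
                        k27_all, list())
  mX <- evidence_matrix(annX, "k27ac")
  expect_true(all(unlist(mX[, c("A", "B")])))
  # empty annotated list -> header-only table
  ann0 <- annotate_snps(snps1[0, ], x$dhs, x$k27, x$ctcf)
  expect_equal(nrow(evidence_matrix(ann0, "k27ac")), 0)
})
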