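test_that("equal seeds give byte-identical landscape files", {
  d1 <- file.path(tempdir(), "det1")
  d2 <- file.path(tempdir(), "det2")
  write_landscape(simulate_landscape(small_config(), seed = 4), d1)
  write_landscape(simulate_landscape(small_config(), seed = 4), d2)
  files <- list.files(d1, recursive = TRUE)
  expect_identical(files, list.files(d2, recursive = TRUE))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # a different seed moves at least the SNP table
  d3 <- file.path(tempdir(), "det3")
  write_landscape(simulate_landscape(small_config(), seed = 5), d3)
  expect_false(identical(readLines(file.path(d1, "snps.tsv")),
                         readLines(file.path(d3, "snps.tsv"))))
})

test_that("every generated file parses with the package readers", {
  ls <- small_landscape()
  dir <- file.path(tempdir(), "parse")
  write_landscape(ls, dir)
  inp <- read_landscape_inputs(dir)
  expect_equal(nrow(inp$snps), nrow(ls$snps))
  expect_equal(nrow(inp$dhs), nrow(ls$dhs))
  expect_equal(nrow(inp$chip_peaks), nrow(ls$chip_peaks))
  expect_equal(nrow(inp$loops), nrow(ls$loops))
  expect_equal(nrow(inp$motifs), nrow(ls$motifs))
  expect_equal(inp$genes$genes$gene_id, ls$genes$genes$gene_id)
})

test_that("full reproducibility makes HC sets equal replicate 1", {
  ls <- simulate_landscape(small_config(background_reproducibility = 1),
                           seed = 2)
  expect_true(all(ls$chip_peaks$reproducible))
  for (mark in c("H3K27Ac", "CTCF")) {
    hc <- hc_sets_for_mark(ls$chip_peaks, mark)
    for (set in hc) {
      rep1 <- ls$chip_peaks[ls$chip_peaks$mark == mark &
                              ls$chip_peaks$cell_line == set$cell_line &
                              ls$chip_peaks$replicate == "rep1", ]
      expect_equal(nrow(set$peaks), nrow(rep1),
                   label = paste(mark, set$cell_line))
    }
  }
})

test_that("HC derivation recovers the planted reproducibility labels", {
  ls <- small_landscape()
  pk <- ls$chip_peaks
  for (mark in c("H3K27Ac", "CTCF")) {
    hc <- hc_sets_for_mark(pk, mark)
    planted <- tapply(pk$reproducible[pk$mark == mark &
                                        pk$replicate == "rep1"],
                      pk$cell_line[pk$mark == mark & pk$replicate == "rep1"],
                      sum)
    derived <- vapply(hc, function(s) nrow(s$peaks), numeric(1))
    expect_equal(unname(derived[names(planted)]), as.numeric(planted))
  }
})

test_that("planted funnel strata are recovered exactly from the files", {
  ls <- small_landscape()
  dir <- file.path(tempdir(), "funnel_files")
  write_landscape(ls, dir)
  inp <- read_landscape_inputs(dir)
  res <- run_snp_funnel(inp$snps, inp$dhs, inp$chip_peaks, inp$loops,
                        inp$genes)
  cfg <- ls$config
  expect_equal(unlist(res$counts),
               c(n_input = cfg$n_snps, n_dhs = cfg$n_dhs,
                 n_dhs_k27ac = cfg$n_k27ac, n_dhs_ctcf = cfg$n_ctcf,
                 n_dhs_k27ac_loop = cfg$n_k27ac_loop,
                 n_dhs_ctcf_loop = cfg$n_ctcf_loop))
  # per-SNP truth labels, not just totals
  ann <- res$annotated
  s <- ann$snps
  truth <- ls$snps$stratum[match(s$rsid, ls$snps$rsid)]
  expect_identical(s$in_dhs, truth != "none")
  expect_identical(rowSums(ann$k27ac_hits) > 0,
                   stats::setNames(truth %in% c("dhs_k27ac", "dhs_k27ac_loop"),
                                   s$rsid))
  expect_identical(rowSums(ann$ctcf_hits) > 0,
                   stats::setNames(truth %in% c("dhs_ctcf", "dhs_ctcf_loop"),
                                   s$rsid))
  loop_truth <- truth %in% c("dhs_k27ac_loop", "dhs_ctcf_loop")
  mark_pos <- rowSums(ann$k27ac_hits) > 0 | rowSums(ann$ctcf_hits) > 0
  expect_identical(unname(rowSums(ann$loop_hits) > 0 & mark_pos), loop_truth)
})

test_that("planted convergence labels are recovered for every loop", {
  ls <- small_landscape()
  for (tab in list(ls$grid_loops, ls$risk_loop_truth)) {
    got <- vapply(seq_len(nrow(tab)), function(i)
      classify_convergence(tab[i, ], ls$motifs), "")
    expect_identical(got, tab$convergence)
  }
})

test_that("planted loop support and filter expectations hold", {
  ls <- small_landscape()
  by_ds <- filter_loops_by_dataset(ls$loops)
  kept_names <- unique(unlist(lapply(by_ds, function(x) x$name)))
  expect_setequal(kept_names,
                  unique(ls$loops$name[ls$loops$keep_expected]))
  set.seed(301)
  idx <- sample(nrow(ls$grid_loops), 10)
  for (i in idx) {
    expect_equal(cross_dataset_support(ls$grid_loops[i, ], by_ds)$support,
                 max(ls$grid_loops$support[i], 1), label = paste("loop", i))
  }
})

test_that("infeasible configurations are rejected up front", {
  expect_error(landscape_config(n_snps = 100, n_dhs = 200), "DHS stratum")
  expect_error(landscape_config(n_k27ac = 50, n_ctcf = 50, n_dhs = 80),
               "mark strata")
  expect_error(landscape_config(n_k27ac_loop = 250, n_ctcf_loop = 100),
               "anchor grid")
  expect_error(landscape_config(risk_loop_spans = c(15e3, 715e3)),
               "desert")
  expect_error(simulate_deletion_expression(small_landscape(), "bogus"),
               "unknown scenario")
})

test_that("scenario effect sizes order the expression responses", {
  ls <- small_landscape()
  fold_of <- function(sc, s) {
    e <- simulate_deletion_expression(ls, sc, seed = s)
    eff <- compute_fold_changes(e)
    eff$fold_change[eff$gene_id == ls$locus$caged_gene]
  }
  for (s in 1:5) {
    f_risk <- fold_of("risk_anchor_deleted", s)
    f_double <- fold_of("double_partner_deleted", s)
    f_single <- fold_of("partner_anchor_deleted", s)
    f_ctrl <- fold_of("control", s)
    expect_gt(f_risk, 3 * f_double)
    expect_gt(f_double, f_single)
    expect_lt(abs(log2(f_single / f_ctrl)), 2.5)
  }
})
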