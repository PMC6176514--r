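mk_exp <- function(mat, n_ctrl = 3, n_del = 3) {
  colnames(mat) <- c(paste0("c", seq_len(n_ctrl)), paste0("d", seq_len(n_del)))
  deletion_experiment(genomic_intervals("chr1", 1000, 2000),
                      control_samples = paste0("c", seq_len(n_ctrl)),
                      deleted_samples = paste0("d", seq_len(n_del)),
                      expression = mat)
}

test_that("fold change is the pseudocounted ratio of group means", {
  # equal library sizes so normalisation is a no-op; gene g2 balances columns
  mat <- rbind(g1 = c(2, 2, 2, 200, 200, 200),
               g2 = c(1000, 1000, 1000, 802, 802, 802))
  eff <- compute_fold_changes(mk_exp(mat))
  expect_equal(eff$fold_change[eff$gene_id == "g1"], 200.5 / 2.5)  # 80.2
  expect_equal(eff$log2fc, log2(eff$fold_change))
})

test_that("an unexpressed gene has fold change exactly 1", {
  mat <- rbind(g1 = c(0, 0, 0, 0, 0, 0), g2 = c(10, 10, 10, 10, 10, 10))
  eff <- compute_fold_changes(mk_exp(mat))
  expect_equal(eff$fold_change[eff$gene_id == "g1"], 1.0)
})

test_that("fold changes are invariant to rescaling a sample column", {
  set.seed(21)
  mat <- matrix(rnbinom(60, mu = 100, size = 10), nrow = 10,
                dimnames = list(paste0("g", 1:10), NULL))
  e1 <- mk_exp(mat)
  mat2 <- mat
  mat2[, 2] <- mat2[, 2] * 7
  mat2[, 5] <- mat2[, 5] * 0.3
  e2 <- mk_exp(mat2)
  # exact in the small-pseudocount limit (the ratio of normalised means is
  # scale-free); the default pseudocount perturbs it only negligibly
  expect_equal(compute_fold_changes(e1, pseudocount = 1e-9)$fold_change,
               compute_fold_changes(e2, pseudocount = 1e-9)$fold_change,
               tolerance = 1e-9)
  expect_equal(compute_fold_changes(e1)$fold_change,
               compute_fold_changes(e2)$fold_change, tolerance = 0.02)
})

test_that("swapping group labels negates every log2 fold change", {
  set.seed(22)
  mat <- matrix(rnbinom(60, mu = 50, size = 10), nrow = 10,
                dimnames = list(paste0("g", 1:10),
                                c(paste0("c", 1:3), paste0("d", 1:3))))
  fwd <- deletion_experiment(genomic_intervals("chr1", 0, 10),
                             paste0("c", 1:3), paste0("d", 1:3), mat)
  rev <- deletion_experiment(genomic_intervals("chr1", 0, 10),
                             paste0("d", 1:3), paste0("c", 1:3), mat)
  expect_equal(compute_fold_changes(fwd)$log2fc,
               -compute_fold_changes(rev)$log2fc, tolerance = 1e-12)
})

test_that("requesting an absent gene names it in the error", {
  mat <- rbind(g1 = rep(5, 6))
  expect_error(compute_fold_changes(mk_exp(mat), genes = c("g1", "gX")),
               "gX")
})

test_that("the experiment container validates its groups", {
  mat <- rbind(g1 = rep(5, 6))
  colnames(mat) <- paste0("s", 1:6)
  expect_error(deletion_experiment(genomic_intervals("chr1", 0, 10),
                                   character(0), "s4", mat), "non-empty")
  expect_error(deletion_experiment(genomic_intervals("chr1", 0, 10),
                                   "s1", "s1", mat), "overlap")
  expect_error(deletion_experiment(genomic_intervals("chr1", 0, 10),
                                   "s1", "sZ", mat), "sZ")
})

test_that("permutation p-values are small only for the perturbed gene", {
  set.seed(23)
  mat <- matrix(rnbinom(120, mu = 200, size = 10), nrow = 20,
                dimnames = list(paste0("g", 1:20), NULL))
  mat[1, 4:6] <- mat[1, 4:6] * 50
  eff <- compute_fold_changes(mk_exp(mat), n_perm = 200, perm_seed = 9)
  expect_lt(eff$p_perm[1], 0.2)   # 3v3 has only 20 distinct splits
  expect_gt(min(eff$p_perm[-1]), 0.02)
})

test_that("window reports rank by |log2fc| with distance tie-breaks", {
  genes <- data.frame(gene_id = paste0("g", 1:5), gene_name = paste0("G", 1:5),
                      chrom = "chr1", strand = "+",
                      start = c(1e6, 1.2e6, 1.4e6, 1.6e6, 5e6),
                      stringsAsFactors = FALSE)
  genes$end <- genes$start + 1e4
  genes$tss_pos0 <- genes$start
  genes$tes_pos0 <- genes$end - 1
  gm <- gene_models(genes, genes[0, c("gene_id", "chrom", "start", "end")])
  eff <- data.frame(gene_id = paste0("g", 1:5),
                    mean_control = 10, mean_deleted = 10,
                    fold_change = c(100, 10, 0.1, 1, 50),
                    stringsAsFactors = FALSE)
  eff$log2fc <- log2(eff$fold_change)
  site <- list(chrom = "chr1", pos0 = 1.3e6)
  rep <- window_report(eff, site, gm)
  expect_equal(rep$gene_id[1], "g1")        # |log2fc| 6.64 wins
  # g2 (up 10x) and g3 (down 10x) tie on |log2fc|; g2 is closer to the site
  expect_equal(rep$gene_id[2:3], c("g2", "g3"))
  expect_false("g5" %in% rep$gene_id)       # outside the 1 Mb window
  expect_equal(attr(rep, "top_responder"), "g1")
  expect_true(attr(rep, "responder_called"))
  # two planted responders are both reported, larger first
  expect_true(which(rep$gene_id == "g2") < which(rep$gene_id == "g4"))
})

test_that("a flat landscape yields no responder call", {
  genes <- data.frame(gene_id = "g1", gene_name = "G1", chrom = "chr1",
                      strand = "+", start = 1e6, end = 1.01e6,
                      tss_pos0 = 1e6, tes_pos0 = 1.01e6 - 1,
                      stringsAsFactors = FALSE)
  gm <- gene_models(genes, genes[0, c("gene_id", "chrom", "start", "end")])
  eff <- data.frame(gene_id = "g1", mean_control = 10, mean_deleted = 10,
                    fold_change = 1.1, log2fc = log2(1.1),
                    stringsAsFactors = FALSE)
  rep <- window_report(eff, list(chrom = "chr1", pos0 = 1.1e6), gm)
  expect_false(attr(rep, "responder_called"))
  expect_warning(window_report(eff, list(chrom = "chr2", pos0 = 1e6), gm),
                 "no genes")
})

test_that("the planted effect is recovered from simulated counts", {
  ls <- small_landscape()
  folds <- vapply(1:20, function(s) {
    e <- simulate_deletion_expression(ls, "risk_anchor_deleted", seed = s)
    eff <- compute_fold_changes(e)
    eff$fold_change[eff$gene_id == ls$locus$caged_gene]
  }, numeric(1))
  expect_gt(mean(folds), 80)
  expect_lt(mean(folds), 120)
  # and the caged gene is the top responder in each run
  site <- ls$locus$site
  tops <- vapply(1:10, function(s) {
    e <- simulate_deletion_expression(ls, "risk_anchor_deleted", seed = s)
    rep <- window_report(compute_fold_changes(e), site, ls$genes)
    attr(rep, "top_responder")
  }, character(1))
  expect_true(all(tops == ls$locus$caged_gene))
})
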