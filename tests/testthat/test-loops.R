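test_that("loop filtering applies span bounds and strict q threshold", {
  loops <- rbind(
    mk_loop("chr1", 100000, 110000, 100000 + 40000, 110000 + 40000,
            q = 0.01, name = "span40k"),
    mk_loop("chr1", 100000, 110000, 100000 + 49999, 110000 + 49999,
            q = 0.01, name = "span49999"),
    mk_loop("chr1", 100000, 110000, 100000 + 50000, 110000 + 50000,
            q = 0.01, name = "span50k"),
    mk_loop("chr1", 100000, 110000, 100000 + 220000, 110000 + 220000,
            q = 0.049, name = "span220k"),
    mk_loop("chr1", 100000, 110000, 100000 + 60000, 110000 + 60000,
            q = 0.05, name = "q05"),
    mk_loop("chr1", 1e6, 1.01e6, 1e6 + 10e6, 1.01e6 + 10e6,
            q = 0.01, name = "span10Mb"),
    mk_loop("chr1", 1e6, 1.01e6, 1e6 + 9.99e6, 1.01e6 + 9.99e6,
            q = 0.01, name = "span9.99Mb"))
  kept <- filter_loops(loops)
  expect_setequal(kept$name, c("span50k", "span220k", "span9.99Mb"))
  expect_true(all(loop_span(kept) >= 50000 & loop_span(kept) < 10e6))
})

test_that("inter-chromosomal records are rejected with a count", {
  loops <- mk_loop("chr1", 0, 10000, 2e5, 2.1e5)
  loops$chrom2 <- "chr2"
  expect_message(out <- filter_loops(loops), "1 inter-chromosomal")
  expect_equal(nrow(out), 0)
})

test_that("missing q-values pass the filter with a warning", {
  loops <- mk_loop("chr1", 0, 10000, 2e5, 2.1e5, q = NA)
  expect_warning(out <- filter_loops(loops), "without q-value")
  expect_equal(nrow(out), 1)
})

test_that("anchor membership distinguishes anchors from the interior", {
  loops <- mk_loop("chr1", 100000, 110000, 400000, 410000)
  expect_equal(anchor_hits("chr1", 105000, loops)$anchor, 1L)
  expect_equal(anchor_hits("chr1", 405000, loops)$anchor, 2L)
  expect_equal(nrow(anchor_hits("chr1", 250000, loops)), 0)  # interior
  expect_equal(nrow(anchor_hits("chr2", 105000, loops)), 0)
})

test_that("cross-dataset support counts matching datasets including its own", {
  q <- mk_loop("chr1", 100000, 110000, 400000, 410000, dataset = "ds1")
  same <- lapply(1:5, function(i) q)
  names(same) <- paste0("ds", 1:5)
  expect_equal(cross_dataset_support(q, same)$support, 5)
  shifted <- mk_loop("chr1", 110000, 120000, 410000, 420000, dataset = "ds2")
  expect_equal(cross_dataset_support(q, list(ds2 = shifted),
                                     slack = 10000)$support, 2)
  expect_equal(cross_dataset_support(q, list(ds2 = shifted),
                                     slack = 5000)$support, 1)
  expect_equal(cross_dataset_support(q, list(ds1 = q))$support, 1)
})

test_that("support is monotone non-decreasing in slack", {
  set.seed(77)
  q <- mk_loop("chr1", 100000, 110000, 400000, 410000, dataset = "ds0")
  others <- lapply(1:6, function(i) {
    off <- floor(runif(1, -40000, 40000))
    mk_loop("chr1", 100000 + off, 110000 + off, 400000 + off, 410000 + off)
  })
  names(others) <- paste0("ds", 1:6)
  supp <- vapply(c(0, 5000, 10000, 20000, 50000), function(sl)
    cross_dataset_support(q, others, slack = sl)$support, numeric(1))
  expect_true(all(diff(supp) >= 0))
})

test_that("motif orientation classes follow the strand pair of anchor top motifs", {
  loop <- mk_loop("chr1", 100000, 110000, 400000, 410000)
  m <- function(...) do.call(rbind, list(...))
  expect_equal(classify_convergence(loop, m(mk_motif("chr1", 105000, "+"),
                                            mk_motif("chr1", 405000, "-"))),
               "convergent")
  expect_equal(classify_convergence(loop, m(mk_motif("chr1", 105000, "+"),
                                            mk_motif("chr1", 405000, "+"))),
               "tandem")
  expect_equal(classify_convergence(loop, m(mk_motif("chr1", 105000, "-"),
                                            mk_motif("chr1", 405000, "+"))),
               "divergent")
  expect_equal(classify_convergence(loop, m(mk_motif("chr1", 105000, "+"))),
               "no_motif")
  expect_equal(classify_convergence(
    loop, m(mk_motif("chr1", 105000, "+"),
            mk_motif("chr1", 404000, "+", score = 8),
            mk_motif("chr1", 406000, "-", score = 8))), "ambiguous")
  # higher-scoring motif wins within an anchor
  expect_equal(classify_convergence(
    loop, m(mk_motif("chr1", 104000, "-", score = 3),
            mk_motif("chr1", 106000, "+", score = 9),
            mk_motif("chr1", 405000, "-"))), "convergent")
})

test_that("convergence is invariant to input anchor order after canonicalisation", {
  swapped <- data.frame(chrom1 = "chr1", start1 = 400000, end1 = 410000,
                        chrom2 = "chr1", start2 = 100000, end2 = 110000,
                        name = "l", q_value = 0.01, dataset = "ds1",
                        stringsAsFactors = FALSE)
  motifs <- rbind(mk_motif("chr1", 105000, "+"), mk_motif("chr1", 405000, "-"))
  expect_equal(classify_convergence(canonicalize_loops(swapped), motifs),
               "convergent")
})

test_that("risk-loop assembly collapses duplicates and flags high confidence", {
  ls <- full_landscape()
  site <- ls$locus$site
  rl <- build_risk_loops(site, filter_loops_by_dataset(ls$loops), ls$motifs)
  expect_equal(nrow(rl), 2)
  expect_equal(rl$span_bp, sort(ls$config$risk_loop_spans))
  expect_equal(rl$support, c(5, 5))
  expect_equal(rl$convergence, c("convergent", "convergent"))
  expect_true(all(rl$high_confidence))
})
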