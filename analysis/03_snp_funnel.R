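#!/usr/bin/env Rscript
# Step 3: the SNP evidence funnel. Each fine-mapped SNP is tested against
# the DHS catalog, then (if in open chromatin) against every H3K27Ac HC
# peak set and every CTCF HC summit window, then against loop anchors of
# the filtered chromatin-interaction datasets. Emits the stage counts and
# the per-SNP x per-dataset evidence matrices.

suppressMessages(library(riskloop))

inp <- read_landscape_inputs("results/landscape")
res <- run_snp_funnel(inp$snps, inp$dhs, inp$chip_peaks, inp$loops,
                      inp$genes)

jsonlite::write_json(as.list(res$counts), "results/funnel_counts.json",
                     auto_unbox = TRUE, digits = NA)
for (mark in c("k27ac", "ctcf")) {
  m <- evidence_matrix(res$annotated, mark)
  f <- sprintf("results/evidence_%s.tsv", mark)
  write.table(m, f, sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s evidence matrix: %d SNPs x %d columns -> %s\n",
              toupper(mark), nrow(m), ncol(m), f))
}

fc <- res$counts
cat(sprintf(paste0("\nFunnel: %d SNPs -> %d in open chromatin -> ",
                   "%d +H3K27Ac / %d +CTCF -> %d / %d in loop anchors\n"),
            fc$n_input, fc$n_dhs, fc$n_dhs_k27ac, fc$n_dhs_ctcf,
            fc$n_dhs_k27ac_loop, fc$n_dhs_ctcf_loop))
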