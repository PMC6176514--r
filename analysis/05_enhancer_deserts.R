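#!/usr/bin/env Rscript
# Step 5: enhancer deserts and target genes. The interiors of the risk
# loops are scanned for H3K27Ac HC peaks (a desert has none over >= 100 kb),
# measured for H3K27me3 coverage, and the genes potentially insulated by the
# loops are predicted. Finally, H3K27Ac sites outside the desert are ranked
# as enhancer-adoption candidates for the post-deletion state.

suppressMessages(library(riskloop))

inp <- read_landscape_inputs("results/landscape")
truth <- jsonlite::read_json("results/landscape/truth.json")
site <- list(chrom = truth$site$chrom, pos0 = truth$site$pos0)

res <- run_snp_funnel(inp$snps, inp$dhs, inp$chip_peaks, inp$loops)
rl <- build_risk_loops(site, res$loops_by_dataset, inp$motifs)
des <- find_deserts(rl, res$k27ac_sets)

k27me3 <- inp$chip_peaks[inp$chip_peaks$mark == "H3K27me3" &
                           inp$chip_peaks$replicate == "rep1", ]
des$k27me3_coverage <- vapply(seq_len(nrow(des)), function(i)
  repressive_coverage(data.frame(chrom = des$chrom1[i],
                                 start = des$interior_start[i],
                                 end = des$interior_end[i]), k27me3),
  numeric(1))
write.table(des, "results/deserts.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("Deserts: %d/%d loop interiors H3K27Ac-free (%s kb), H3K27me3 coverage %s\n",
            sum(des$is_desert), nrow(des),
            paste(round(des$interior_len / 1e3), collapse = "/"),
            paste(round(des$k27me3_coverage, 2), collapse = "/")))

targets <- predict_targets(site, rl, inp$genes)
write.table(targets, "results/target_genes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("Predicted targets: %d genes (%d within loops) -> results/target_genes.tsv\n",
            nrow(targets), sum(targets$basis == "within_loop")))

cand <- adoption_candidates(site, des[which.max(des$interior_len), ],
                            res$k27ac_sets, res$annotated)
write.table(cand, "results/adoption_candidates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf(paste0("Nearest outside H3K27Ac site: %.0f kb from the deleted ",
                   "site, risk-SNP-bearing: %s\n"),
            cand$distance_bp[1] / 1e3, cand$contains_risk_snp[1]))
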