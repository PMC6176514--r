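#!/usr/bin/env Rscript
# Step 4: loops anchored at the risk CTCF site. Loops are filtered per
# interaction dataset (span 50 kb - 10 Mb, q < 0.05), matched across
# datasets with one 10-kb bin of slack, and classified by CTCF motif
# orientation at the anchors; high-confidence risk loops are those
# supported by >= 2 datasets.

suppressMessages(library(riskloop))

inp <- read_landscape_inputs("results/landscape")
truth <- jsonlite::read_json("results/landscape/truth.json")
site <- list(chrom = truth$site$chrom, pos0 = truth$site$pos0)

by_ds <- filter_loops_by_dataset(inp$loops)
cat("Filtered loops per dataset:",
    paste(names(by_ds), vapply(by_ds, nrow, numeric(1)), collapse = ", "),
    "\n")

rl <- build_risk_loops(site, by_ds, inp$motifs)
write.table(rl, "results/risk_loops.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("\n%d risk loops anchored at %s:%d -> results/risk_loops.tsv\n",
            nrow(rl), site$chrom, site$pos0))
print(rl[, c("name", "span_bp", "support", "convergence",
             "high_confidence")])
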