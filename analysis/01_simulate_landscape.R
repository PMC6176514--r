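#!/usr/bin/env Rscript
# Step 1: generate the labelled synthetic regulatory landscape under the
# study conditions (2,181 fine-mapped SNPs; 9 ChIP datasets per mark in
# duplicate; 5 chromatin-interaction datasets; the two-loop deletion locus)
# and write every input file the downstream steps consume.

suppressMessages(library(riskloop))

seed <- 1
outdir <- "results/landscape"

ls <- simulate_landscape(landscape_config(), seed = seed)
paths <- write_landscape(ls, outdir)

cat("Landscape written to", outdir, "\n")
print(ls)
cat("\nPlanted funnel strata (ground truth for steps 2-3):\n")
print(table(ls$snps$stratum))
cat(sprintf("\nDeletion locus: risk CTCF site at %s:%d, loops of %s kb,\n",
            ls$locus$site$chrom, ls$locus$site$pos0,
            paste(ls$config$risk_loop_spans / 1e3, collapse = " and ")))
cat(sprintf("caged gene '%s', adoption enhancer %.0f kb upstream.\n",
            ls$locus$caged_gene, ls$config$enhancer_offset / 1e3))
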