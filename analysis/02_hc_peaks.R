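#!/usr/bin/env Rscript
# Step 2: derive high-confidence (HC) peaks -- those present in both
# replicates -- for every ChIP dataset, and classify their genomic context
# against the gene models (promoter / exon / TTS / intron / intergenic).

suppressMessages(library(riskloop))

inp <- read_landscape_inputs("results/landscape")

hc_k27 <- hc_sets_for_mark(inp$chip_peaks, "H3K27Ac")
hc_ctcf <- hc_sets_for_mark(inp$chip_peaks, "CTCF")

classes <- summarize_peak_classes(c(hc_k27, hc_ctcf), inp$genes)
write.table(classes, "results/peak_classes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("HC peak sets: %d H3K27Ac datasets (%d-%d peaks), %d CTCF (%d-%d)\n",
            length(hc_k27),
            min(classes$n_peaks[classes$mark == "H3K27Ac"]),
            max(classes$n_peaks[classes$mark == "H3K27Ac"]),
            length(hc_ctcf),
            min(classes$n_peaks[classes$mark == "CTCF"]),
            max(classes$n_peaks[classes$mark == "CTCF"])))
cat("Most peaks are intronic/intergenic, with a small promoter fraction:\n")
print(round(colMeans(classes[, grep("^frac_", names(classes))]), 3))
cat("Per-dataset table written to results/peak_classes.tsv\n")
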