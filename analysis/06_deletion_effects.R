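#!/usr/bin/env Rscript
# Step 6: expression consequences of anchor deletions. For each CRISPR
# scenario (risk anchor, one partner anchor, both partner anchors, control)
# simulate 3v3 RNA-seq counts, compute fold changes of all genes within
# +/- 1 Mb of the risk site, and call the top responder; then summarise
# estimator behaviour over 50 replicate simulations.

suppressMessages(library(riskloop))

seed <- 1
ls <- simulate_landscape(landscape_config(), seed = seed)
inp <- read_landscape_inputs("results/landscape")
site <- ls$locus$site
rl <- build_risk_loops(site, filter_loops_by_dataset(inp$loops), inp$motifs)

scenarios <- names(ls$config$scenario_effects)

# one representative run: the ranked +/- 1 Mb window report per scenario
reports <- lapply(scenarios, function(sc) {
  e <- simulate_deletion_expression(ls, sc, n_reps = 3, seed = seed * 1000)
  eff <- compute_fold_changes(e)
  rep <- window_report(eff, site, inp$genes, rl)
  rep$scenario <- sc
  rep
})
tab <- do.call(rbind, reports)
write.table(tab, "results/deletion_effects.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# estimator summary over 50 seeded simulations per scenario
n_runs <- 50
summ <- do.call(rbind, lapply(scenarios, function(sc) {
  folds <- vapply(seq_len(n_runs), function(r) {
    e <- simulate_deletion_expression(ls, sc, n_reps = 3,
                                      seed = seed * 1000 + r)
    eff <- compute_fold_changes(e)
    eff$fold_change[eff$gene_id == ls$locus$caged_gene]
  }, numeric(1))
  data.frame(scenario = sc, true_effect = ls$config$scenario_effects[[sc]],
             mean_fold = mean(folds), sd_fold = sd(folds),
             min_fold = min(folds), max_fold = max(folds))
}))
write.table(summ, "results/scenario_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("Caged-gene fold change by scenario (50 simulations each):\n")
print(summ, row.names = FALSE, digits = 3)
top <- tab[tab$scenario == "risk_anchor_deleted" & tab$rank == 1, ]
cat(sprintf(paste0("\nRisk-anchor deletion: top responder %s at %.0f-fold; ",
                   "all other window genes stay near 1-fold.\n"),
            top$gene_id, top$fold_change))
cat("Tables written to results/deletion_effects.tsv and results/scenario_summary.tsv\n")
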