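# riskloop

Regulatory annotation of disease-risk SNPs and detection of CTCF-anchored
repressive chromatin loops, with expression analysis of loop-anchor
deletions.

## What this is for

Fine-mapping of GWAS loci yields thousands of candidate risk SNPs, almost
all non-coding. The ones most likely to be functional sit in active
regulatory elements — and a particularly interesting subset sits in the
anchors of CTCF-mediated chromatin loops, where a variant can perturb 3D
insulation of an entire locus. `riskloop` is for regulatory genomicists who
want to run that triage and its downstream consequences as one tested
pipeline:

1. **High-confidence (HC) peaks** — ChIP-seq peaks present in both
   replicates (`derive_hc_peaks`), classified by genomic context
   (promoter / exon / TTS / intron / intergenic, fixed priority).
2. **The SNP funnel** (`annotate_snps`, `funnel_counts`) — nested evidence
   stages per SNP base: open chromatin (DHS) → H3K27Ac HC peaks (full
   intervals) and CTCF HC peaks (±1 kb summit windows) → chromatin-loop
   anchors, per dataset roster.
3. **Loops** (`filter_loops`, `cross_dataset_support`,
   `classify_convergence`) — span filter 50 kb ≤ span < 10 Mb at q < 0.05,
   anchor matching across interaction datasets with one 10-kb bin of slack,
   and CTCF motif orientation at the anchors: (+,−) = convergent, the
   loop-extrusion configuration.
4. **Enhancer deserts** (`find_deserts`, `repressive_coverage`,
   `predict_targets`, `adoption_candidates`) — H3K27Ac-free loop interiors
   ≥ 100 kb, their H3K27me3 coverage, the genes whose TSS they sequester,
   and the outside enhancers a caged promoter could adopt after anchor
   deletion.
5. **Deletion effects** (`compute_fold_changes`, `window_report`) — per-gene
   `fold = (mean(deleted)+0.5)/(mean(control)+0.5)` on library-size-
   normalised counts, ranked over the ±1 Mb window around the deleted site.

A first-class synthetic-data module (`simulate_landscape`,
`simulate_deletion_expression`) generates a fully labelled regulatory
landscape — replicate peak pairs with controlled reproducibility, SNPs
planted at known funnel depths, convergent-motif loops, an enhancer-desert
locus with a caged gene, and negative-binomial expression with planted
effects — so every stage is validated against ground truth.

File formats: BED3/6, ENCODE narrowPeak, BEDPE (q-value in column 8),
tab-separated SNP tables (1-based, converted to 0-based internally), motif
BED6, minimal Gencode-style GTF. All readers/writers round-trip
byte-identically.

## Worked example

```r
library(riskloop)

ls <- simulate_landscape(landscape_config(), seed = 1)
res <- run_snp_funnel(ls$snps, ls$dhs, ls$chip_peaks, ls$loops, ls$genes)
res$counts
#>   n_input n_dhs n_dhs_k27ac n_dhs_ctcf n_dhs_k27ac_loop n_dhs_ctcf_loop
#> 1    2181   443         222         93              203              85
```

2,181 fine-mapped SNPs funnel down to 443 in open chromatin, 222 of those
also in an H3K27Ac HC peak (203 in a loop anchor) and 93 in a CTCF summit
window (85 in a loop anchor) — exactly the strata planted by the generator.

```r
site <- ls$locus$site        # the risk CTCF site, chr1:7005000
rl <- build_risk_loops(site, filter_loops_by_dataset(ls$loops), ls$motifs)
rl[, c("name", "span_bp", "support", "convergence", "high_confidence")]
#>          name span_bp support convergence high_confidence
#> 1 risk_loop_1  300000       5  convergent            TRUE
#> 2 risk_loop_2  715000       5  convergent            TRUE
```

The risk site anchors a 300-kb and a 715-kb loop, each supported by all 5
interaction datasets with convergent CTCF motifs. Both interiors are
enhancer deserts (290 and 705 kb without a single H3K27Ac peak, ~94%
covered by H3K27me3), and the nearest outside H3K27Ac site — 64 kb from the
deleted site, carrying risk SNPs — is the rank-1 enhancer-adoption
candidate.

```r
e <- simulate_deletion_expression(ls, "risk_anchor_deleted", n_reps = 3, seed = 7)
rep <- window_report(compute_fold_changes(e), site, ls$genes, rl)
head(rep[, c("gene_id", "fold_change", "in_loop", "rank")], 3)
#>      gene_id fold_change in_loop rank
#> 1 gene_caged  89.2799212    TRUE    1
#> 2   gene_up3   0.5953059   FALSE    2
#> 3   gene_up5   1.5721767   FALSE    3
```

Deleting the risk anchor releases the caged gene (~90-fold here; unbiased
around the planted 100-fold across simulations) while every other gene in
the ±1 Mb window stays near 1-fold. Deleting the partner anchors instead
gives only 2-fold (single) or 7-fold (double) increases — the repressive
function lives in the risk-associated anchor.

## The analysis, step by step

`analysis/01_simulate_landscape.R` … `06_deletion_effects.R` run the chain
as numbered scripts, writing intermediate tables (peak context fractions,
evidence matrices, risk loops, deserts, target genes, deletion reports)
under `results/`.

## License

MIT (see `LICENSE`).
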