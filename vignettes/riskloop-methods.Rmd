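---
title: "Methods: from risk SNPs to repressive CTCF loops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from risk SNPs to repressive CTCF loops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Most disease-risk variants found by GWAS and refined by fine-mapping fall in
non-coding DNA. A small subset of them are plausibly *functional*: they sit
in active regulatory elements, and some sit precisely in the anchors of
CTCF-mediated chromatin loops, where a single-base change can perturb the 3D
insulation of a whole locus. `riskloop` implements the analysis chain that
identifies such variants and quantifies what happens to nearby genes when a
loop anchor is removed:

1. derive *high-confidence* (HC) ChIP-seq peak sets from replicate pairs;
2. run the nested SNP evidence funnel (open chromatin → histone
   acetylation / CTCF occupancy → loop anchors);
3. filter and characterise chromatin loops (span, significance,
   cross-dataset support, convergent CTCF motif orientation);
4. detect *enhancer deserts* — large H3K27Ac-free loop interiors covered by
   the repressive mark H3K27me3 — and predict the genes they sequester;
5. rank candidate enhancers a caged promoter could adopt after the anchor
   is deleted, and measure per-gene expression fold changes in deletion
   experiments.

Every step is exercised end-to-end on a synthetic landscape with planted
ground truth, because the raw study-scale datasets this pipeline is designed
for are not redistributable at package scale.

# Coordinates and interval algebra

All internal coordinates are 0-based half-open (BED-native). 1-based formats
(SNP tables, GTF) are converted on read and back-converted on write; every
reader/writer pair round-trips byte-identically on canonical files. A single
convention removes the class of off-by-one errors that otherwise accumulates
when BED, GTF and variant coordinates are mixed.

"Overlap" always means ≥ 1 bp, with strict half-open boundaries: `[100, 200)`
and `[200, 300)` do not overlap. No minimum-overlap fraction is applied
anywhere. Membership filtering (`filter_overlapping`) keeps original query
coordinates by default (the `-wa -u` idiom), because downstream steps need
the original summit offsets; a clipped-intersection variant exists behind a
flag. Chromosome names are compared verbatim. Overlap joins are delegated to
`GenomicRanges`/`IRanges`; the test suite checks them against brute-force
all-pairs and per-base oracles.

# High-confidence peaks

A ChIP-seq peak is *high-confidence* when it is present in both biological
replicates, operationalised as ≥ 1 bp overlap with any partner-replicate
peak. Reported HC coordinates are those of replicate 1, not the clipped
intersection: this preserves summit offsets, which the CTCF stage of the
funnel needs. (A `coords = "merged"` mode reports the union span instead;
the choice between the two cannot be recovered from typical methods
descriptions, so both are implemented with replicate 1 as the default.)
Although the two argument orders report different coordinates, they identify
the same set of reproducible events — a property the tests assert via the
bipartite overlap graph.

Genomic context is classified HOMER-style against gene models, with the
category set reduced to promoter > exon > TTS > intron > intergenic in fixed
priority (the richer HOMER vocabulary collapses mostly into
intron/intergenic in this analysis, and "other" categories map to
intergenic). The promoter is 1 kb upstream to 100 bp downstream of the TSS,
strand-aware; the TTS window is ± 1 kb of the transcription end site; ties
across genes go to the nearest TSS. All three windows are configurable.

# The SNP funnel

Each fine-mapped SNP is a 1-bp interval `[pos0, pos0 + 1)`; indels and
multi-base variants are out of scope. The funnel is deliberately *nested*:

* **Stage 1 — open chromatin.** The SNP base must fall inside a DHS. DHS
  peaks are narrow and mark the actual transcription-factor platform, so
  this stage removes SNPs that ride along at the margins of broad histone
  peaks. The DHS catalog is taken as provided (no merging on read).
* **Stage 2 — mark evidence**, only for stage-1 SNPs, per dataset roster:
  H3K27Ac membership uses the *full HC peak interval*, while CTCF uses
  ± 1 kb windows around HC peak *summits* (midpoint when a summit is
  absent). The asymmetry is deliberate: acetylation is a regional signal,
  CTCF occupancy is a point signal. The ± 1 kb window is closed on both
  sides (2 kb + 1 bp wide); a SNP exactly 1 kb from a summit counts, one at
  1,001 bp does not.
* **Stage 3 — loop anchors**, per interaction dataset: the SNP base inside
  either anchor interval of a filtered loop. Loop interiors do not count.

Stage counts report each SNP once regardless of how many datasets hit it;
"union across datasets" means hit in ≥ 1 roster entry, while the per-dataset
columns are retained in the evidence matrices. Funnel monotonicity
(`n_input ≥ n_dhs ≥ n_mark ≥ n_mark+loop`) is asserted on every computation,
not assumed.

# Loops

Loops are intra-chromosomal anchor pairs with a q-value; records are
canonicalised so anchor 1 precedes anchor 2, making every anchor-dependent
result invariant to input order. The filter keeps spans in
`[50 kb, 10 Mb)` at `q < 0.05` (strict on both), the standard significance
screen for bin-level contact calls; q-values absent from pre-filtered
datasets pass with a warning. Span is measured **midpoint-to-midpoint** of
the anchors: anchors are typically fixed 10-kb matrix bins, so midpoints are
the stable quantity under small boundary changes.

Cross-dataset support asks, per dataset, whether any loop matches both
anchors within a slack of one 10-kb bin (midpoint distance ≤ 10 kb,
configurable); support counts the query's own dataset and is monotone in the
slack. A *high-confidence risk loop* is anchored at a risk site and
supported by ≥ 2 datasets (configurable; the exemplar loops in this style of
analysis are typically found in all five).

Motif orientation takes the highest-scoring CTCF motif overlapping each
anchor: `(+, −)` is convergent (the loop-extrusion configuration), `(+, +)`
or `(−, −)` tandem, `(−, +)` divergent; an anchor without a motif yields
`no_motif`, and a tied top score on opposite strands yields `ambiguous`.
Anchor membership uses the bin intervals themselves, not extended regions —
CTCF sites 10 kb outside an anchor do not count.

# Enhancer deserts, targets, adoption

The desert interior is the region **between the inner anchor edges**
(`[end1, start2)`): the risk CTCF site itself lives in an anchor, not in the
desert, and browser-level evidence is ambiguous at anchor edges, so the
conservative interior is used. A desert has zero H3K27Ac HC peaks (union of
the roster) and an interior of at least 100 kb (default; observed deserts
are in the 200–600 kb range, and the floor keeps short interiors from
qualifying vacuously). H3K27me3 coverage is reported as a continuous
merged-bases fraction; no boolean "covered" call is made because no
principled threshold exists.

Target-gene prediction uses the **TSS position**, not the gene span, so
calls at loop edges are unambiguous: a gene is `within_loop` when its TSS
falls in the full span of any risk loop, and `within_window` when its TSS is
within ± 1 Mb of the site; `within_loop` wins on overlap.

Adoption candidates are the H3K27Ac HC sites (merged across the roster)
outside the desert interior, ranked by gap distance to the deleted site and
flagged when they contain a SNP with acetylation-stage evidence. The module
reports observables only — it does not adjudicate between new-enhancer
formation and adoption of a pre-existing enhancer.

# Deletion expression analysis

The expression layer is deliberately the *descriptive* fold-change analysis
of the locus: per-gene
`fold = (mean(deleted) + c) / (mean(control) + c)` on library-size-normalised
counts (columns scaled to the mean library size), with pseudocount
`c = 0.5`. Genome-wide differential-expression modelling (edgeR-style
dispersion estimation, batch correction) is out of scope; an optional
label-permutation p-value (≥ 1,000 shuffles, seeded) is available for locus
tables. The pseudocount keeps silent genes at fold 1 and bounds the
statistic; because the normalisation target is data-dependent, column
rescaling leaves fold changes invariant exactly in the small-pseudocount
limit and negligibly perturbed at the default for expressed genes — both
regimes are tested. Window reports rank genes within ± 1 Mb of the site by
|log2 fold|, break ties by genomic distance (the data never produce exact
ties, but the rule is fixed), and call no responder when the top gene moves
less than 2-fold in either direction.

# The synthetic landscape

`simulate_landscape()` plants every truth label the pipeline recovers. Its
defaults are the study conditions: 2,181 fine-mapped SNPs, of which 443 in
open chromatin, 222 also in H3K27Ac HC peaks (203 of those in loop anchors)
and 93 in CTCF summit windows (85 in anchors); 9 cell-line/condition ChIP
datasets per mark, each in duplicate (18 datasets per mark); 5
chromatin-interaction datasets; a deletion locus whose risk CTCF anchor
holds a 300-kb and a 715-kb convergent loop present in all 5 datasets, with
an H3K27Ac-free, H3K27me3-tiled interior, a caged gene just inside the
desert, and the nearest outside enhancer (risk-SNP-bearing) ~65 kb from the
site — between the ~60 and ~70 kb exemplars of the two deletion loci this
locus emulates.

Geometry is a deterministic skeleton with seeded jitter. Two chromosomes are
used: chr1 (14 Mb) holds a 10-kb anchor-cell grid for loop-anchored SNPs,
the deletion locus, and two whole-chromosome loops straddling the 10-Mb span
ceiling; chr2 (10 Mb) holds 4-kb slots for non-loop SNPs, a background
region of replicate peak pairs with a controlled 80% reproducibility rate
(irreproducible peaks are ≥ 10 kb from any partner peak by 20-kb spacing),
and loops straddling the 50-kb span floor and the 0.05 q threshold. chr1 is
14 Mb rather than 10 Mb purely so that a just-under-10-Mb loop fits with
both anchors in SNP-free territory. Slot spacing (4 kb against a maximum
evidence reach of ~1.7 kb) guarantees that evidence planted for one SNP can
never leak onto a neighbour, which is what makes exact stratum recovery a
meaningful test rather than a statistical one. One oriented CTCF motif is
planted per used anchor cell, with anchor-2 cells assigned by a
collision-free deterministic schedule, so convergence labels are
unambiguous by construction and must be recovered at 100%.

Replicate 2 of each planted peak jitters bounds by N(0, 50 bp) and summits
by N(0, 20 bp) — small against peak widths of 0.6–2 kb, so reproducibility
is preserved by construction. Expression is negative-binomial with
dispersion 0.1 (a typical cell-line replicate value; the underlying clonal
experiments give no variance model to fit) around fixed per-gene baselines;
the caged gene's baseline is 40 counts and its mean is multiplied by the
scenario's true effect — 100 (risk anchor deleted), 2 (one partner anchor),
7 (both partner anchors), 1 (control) — matching the qualitative hierarchy
that only removal of the risk-associated anchor releases the caged gene. A
300-gene backbone keeps the library size large relative to any single-gene
perturbation, as in real RNA-seq, so library-size normalisation does not
distort locus fold changes. With 3v3 replicates at this dispersion a single
fold-change estimate has roughly 25% ratio noise; the estimator is unbiased
at the planted 100-fold effect, which is why parameter-recovery checks
average over 50 seeded simulations while top-responder identity (a 6.6 vs
~0.3 |log2| contrast) is asserted per run.

What the generator does **not** emulate: correlated replicate structure and
batch effects, signal-strength gradients across cell lines, GC/mappability
artefacts, LD structure among SNPs, nested TAD hierarchies, distance-decay
in contact frequency, and indirect (trans) expression changes after a
deletion. Passing tests therefore demonstrate that the pipeline's logic is
correct against planted truth under clean conditions, not that it is robust
to every artefact of real data.

# Problem sizes and determinism

The shipped analysis and tests run the full study-scale landscape (2,181
SNPs, ~1,800 peak records, ~900 loop records) plus a reduced landscape for
unit tests, and 50-replicate simulation batches for the expression layer —
sizes chosen so the whole suite completes in well under a minute per
component on a laptop. Every stochastic step takes an explicit seed;
regenerating a landscape with the same seed is byte-identical, file by
file.

# Reproducing the numbers

`scripts/acceptance.R --seed <int> --out <path>` regenerates the landscape,
reruns the funnel from the written files, assembles risk loops, deserts and
adoption candidates, simulates all four deletion scenarios 50 times and
writes every headline quantity as JSON. The numbered scripts under
`analysis/` run the same chain step by step with intermediate tables under
`results/`.
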