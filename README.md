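# pluroadmap

Charting chromatin accessibility dynamics and cell-fate composition along a
staged primed-to-naive pluripotency transition.

Human pluripotent stem cells exist in a post-implantation-like *primed*
state and a pre-implantation-like *naive* state. Resetting primed cells to
the naive state passes through heterogeneous intermediates: chromatin opens
and closes stage by stage, lineage signatures (epiblast, trophectoderm,
primitive endoderm) flicker on in subpopulations, and the naive-like
fraction gradually takes over the culture. `pluroadmap` implements the
bespoke computational layer of such a roadmap analysis as a tested,
reusable R package, and exercises it end to end on seeded synthetic data
generators with planted ground truth, so every stage of the pipeline has a
recoverable right answer.

## What it computes

**Open/closed chromatin charting.** Given a peak-by-sample RPKM matrix and
a size-matched matrix over shuffled background regions (placed by
`shuffle_background()`, which excludes the peak set), the empirical false
discovery rate at a candidate threshold *t* is

```
eFDR(t) = #{background >= t} * (N_peak / N_bg) / #{peak >= t}
```

`calibrate_open_threshold()` returns the smallest observed value with
eFDR <= alpha (default 1%). Stage-merged values at or above the threshold
are *open*; below, *closed*. `classify_dynamics()` then labels each locus
CO (closed-to-open), OC (open-to-closed), PO (permanently open), PC
(permanently closed), or COMPLEX (multiple switches), and
`assign_promoters()` maps loci onto TSS +/- 3 kb windows.

**Signature scoring.** For a gene set, `bulk_signature_score()` min-max
scales each retained gene across the sample panel,
`s_gj = (x_gj - min_g) / (max_g - min_g)`, keeping genes with FPKM >= 5 in
at least one sample, and averages over genes — a score in [0, 1] per
sample. `cell_module_score()` is the single-cell analogue: mean
log-normalized expression of the set minus a size-matched, expression-bin
matched control set. `select_tsc_markers()` keeps genes with
log2((nTSC+1)/(hES+1)) > 3, log2((nTSC+1)/(pTSC+1)) > 2.5,
log2((EVT+1)/(nTSC+1)) < -1.5 and log2((ST+1)/(nTSC+1)) < -1.5.

**Expression utilities.** FPKM >= 5 expressed-gene filtering, temporal
k-means (k = 6, k-means++ seeding, per-gene z-scored log2(FPKM+1)),
top-2000-variance feature selection, Pearson sample correlation.

**Single-cell roadmap.** `qc_filter_cells()` applies nFeature > 2500,
1000 < nCount < 100000, pctMT < 10, then removes genes detected in fewer
than 10 retained cells and ribosomal (RPL/RPS) genes.
`assign_lineage()` labels each cell by its best-scoring signature
(naive / primed / TE / PrE), and `lineage_proportions()` tracks the
composition per stage.

**Synthetic data.** `simulate_cad_dataset()`, `simulate_bulk_signatures()`,
`simulate_marker_panel()`, `simulate_cell_matrix()` and
`simulate_temporal_patterns()` are seeded, pure generators that plant
exact class proportions (largest-remainder allocation) and return truth
objects for recovery testing.

## Worked example

```r
library(pluroadmap)

gm     <- genome_model(paste0("chr", 1:4), rep(3e6, 4))
stages <- c("pESC", "day6", "day8", "day10", "nESC")
smap   <- stage_map(stages, setNames(rep(stages, each = 2),
                    paste0(rep(stages, each = 2), "_rep", 1:2)))

cad <- simulate_cad_dataset(gm, 2000,
         c(CO = .25, OC = .25, PO = .25, PC = .25), smap, seed = 7)
thr <- calibrate_open_threshold(cad$peaks, cad$background, alpha = 0.01)
thr
#> open/closed threshold: 5.339 RPKM (eFDR 0.009958 at alpha 0.01;
#>   20000 peak / 20000 background entries)

calls  <- binarize_accessibility(merge_replicates(cad$peaks, smap), thr)
labels <- classify_dynamics(calls)
mean(as.character(labels) == as.character(cad$truth$labels[names(labels)]))
#> [1] 0.9985
```

The calibrated threshold (5.34 RPKM here) is the smallest observed value
at which scaled background exceedances are at most 1% of peak
exceedances; with it, 99.85% of the 2000 loci recover their planted
CO/OC/PO/PC class. On the real staged ATAC matrices this package models,
the same calibration yields a genome-wide RPKM threshold in the low tens.

The numbered drivers under `analysis/` narrate the full workflow —
simulation and format round-trips, chromatin dynamics, signature scores
and marker selection, temporal clustering, and the single-cell endpoint
(planted 93% naive / 3% primed / 2% TE / 2% PrE; the run above recovers
92.89 / 3 / 2 / 2.11 after QC) — writing their tables under `results/`:

```sh
Rscript analysis/01_simulate_data.R
Rscript analysis/02_chromatin_dynamics.R   # ... through 05
```

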