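---
title: "Methods: chromatin and lineage roadmapping of the primed-to-naive transition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin and lineage roadmapping of the primed-to-naive transition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pluroadmap)
```

`pluroadmap` models the computational core of a staged primed-to-naive
pluripotency roadmap: deciding, per ATAC-seq locus and per stage, whether
chromatin is open or closed; classifying each locus's trajectory;
scoring gene signatures on bulk and single-cell expression; and tracking
which lineage identity each cell carries as the transition proceeds.
This vignette explains the models and the choices behind them.

## Open/closed calling by empirical FDR

ATAC-seq RPKM over a peak has no natural "open" cutoff: coverage noise
varies between experiments. The package therefore calibrates the cutoff
against the genome's own null. For every peak, a background region of
identical length is placed uniformly at random on the same chromosome,
rejecting placements that touch any peak or a previously placed
background (`shuffle_background()`; rejection sampling, seeded, with an
explicit failure after `max_attempts`). Quantifying the same samples over
those regions yields a background matrix whose entries are draws from the
closed-chromatin null.

Pooling all entries of both matrices, the empirical FDR at a candidate
threshold $t$ is

$$\mathrm{eFDR}(t) \;=\; \frac{\#\{bg \ge t\}\cdot N_{peak}/N_{bg}}{\#\{peak \ge t\}}$$

— the number of background entries at or above $t$, rescaled to the peak
matrix size, relative to the peak entries called open. Because eFDR is a
step function that changes only at observed values, candidates are
restricted to the sorted distinct observed values; this is lossless and
makes an exhaustive-sweep oracle finite, which the test suite uses to
verify the implementation exactly. `calibrate_open_threshold()` returns
the smallest candidate with at least one peak exceedance and
$\mathrm{eFDR}\le\alpha$ (default $\alpha = 0.01$). Pooling across all
samples (rather than per-sample calibration) reflects that a single
genome-wide threshold governs all downstream open/closed calls; the
per-sample variant would yield stage-dependent thresholds and is
deliberately not implemented.

Equality at the threshold counts as *open*. The rule "below → closed,
above → open" leaves the boundary undefined; since the calibrated
threshold is itself an observed value at which the eFDR guarantee holds,
the value attaining it is treated as signal. The choice is fixed and
tested (`binarize_accessibility()`).

Replicates are merged as the arithmetic mean of their RPKM columns,
a matrix-level stand-in for pooling replicate alignments before
quantification; the two differ when replicate library sizes are very
unbalanced, a divergence accepted for simplicity.

## Dynamics classes

Over $S \ge 2$ temporally ordered stages, each locus's open/closed vector
is classified: PO (open everywhere), PC (closed everywhere), CO (exactly
one closed→open switch), OC (exactly one open→closed switch), and
COMPLEX otherwise. Loci with multiple switches are *not* forced into the
four canonical groups, because non-monotone trajectories are ambiguous;
COMPLEX makes them visible instead. Reversing stage order exchanges CO
and OC and fixes the rest — a symmetry the tests assert over every
pattern up to $S = 5$.

Promoter assignment uses windows of half-width $w$ (default 3000 bp)
around the TSS, in 0-based half-open coordinates $[tss-w,\,tss+w)$. At
$w = 0$ that interval is empty, so the window always covers at least the
TSS base itself; for $w > 0$ this convention coincides exactly with the
half-open window. For minus-strand genes the caller supplies the
annotated transcript end as the TSS. Overlap is delegated to IRanges.

## Signature scores

Bulk scores are panel-relative: each retained gene is min-max scaled
across exactly the samples being compared, and the score is the mean over
genes, hence in $[0,1]$ with 0/1 attained at the panel extremes. Genes
must reach FPKM $\ge 5$ in at least one panel sample to be retained;
constant genes (max = min) make the formula undefined and are dropped
with a warning rather than scored 0, a logged and counted choice. Gene
symbols match exactly and case-sensitively; aliasing is out of scope.
Min-max scaling is invariant to per-gene positive affine transforms, a
property the tests exercise over random transforms.

The single-cell module score log-normalizes counts per cell
($\log(1 + 10^4\,c/\mathrm{total})$), bins genes into 24 equal-frequency
average-expression bins, draws 100 control genes per set gene from the
matching bin, and reports mean(set) − mean(pooled controls) per cell.
Under the null it is centered at zero; the defaults (24 bins,
100 controls) are the conventional control-set-score defaults. The draw
is seeded and deterministic.

TSC markers are selected by four strict log2-ratio inequalities with a +1
pseudocount (thresholds 3, 2.5, −1.5, −1.5): strongly up in naive-derived
TSC versus both pluripotent states, strongly down in both differentiated
trophoblast derivatives. A ratio landing exactly on a threshold fails —
the inequalities are strict, and the boundary is tested.

## Temporal clustering and expression utilities

Trajectory clustering targets *shape*: FPKM is transformed to
$\log_2(\mathrm{FPKM}+1)$ and z-scored per gene before k-means
(default $k = 6$). The transform is a documented choice — clustering raw
FPKM would group by magnitude, not dynamics — and is the main divergence
risk versus implementations that cluster unstandardized values. Seeding
uses k-means++ into Lloyd iterations with `n_init` restarts, keeping the
best within-cluster sum of squares; plain random-point starts proved
unable to seed six tight planted clusters reliably, whereas k-means++
recovers them across seeds. Constant genes carry no shape and are dropped
with a warning. Top-variance selection ranks by variance of
$\log_2(v+1)$ with lexicographic id tie-breaks, so selections are
reproducible; sample correlation is Pearson on the same scale after the
expressed-gene filter.

## Single-cell QC and lineage assignment

Cells are retained iff nFeature > 2500, 1000 < nCount < 100000 and
pctMT < 10 — all strict, matching the stated cutoffs; then genes detected
in fewer than 10 retained cells are discarded and ribosomal genes
removed. The order (cells first, then genes) changes the result and is
therefore fixed. Mitochondrial genes are recognized by the `MT-` symbol
prefix and ribosomal by `RPL`/`RPS`, the standard human conventions; both
patterns are arguments.

Lineage assignment is per-cell: the argmax over the four signature
scores, with exact ties — and optionally margins below `min_margin` —
left `unassigned`. A cluster-level annotation (majority vote within a
clustering) can be layered on top, but the per-cell rule is what the
recovery tests exercise against planted truth. Proportions are tabulated
per stage over all labels including `unassigned`; dropping unassigned
cells and renormalizing is an explicit option, never silent.

## Synthetic data: what it emulates, and what it does not

The generators are pure functions of (parameters, seed) and return truth
objects sufficient to predict every downstream output.

* **Accessibility** (`simulate_cad_dataset()`): background and
  closed-state entries are Exponential(λ = 1); open entries are
  N(μ = 50, σ = 5) truncated at zero. No distributional form is implied
  by real ATAC data — these were chosen as the simplest separable
  null/signal pair with tunable overlap. The default μ places the open
  mean near ten times the background 99th percentile, mimicking the clear
  peak-vs-background separation real staged ATAC matrices show. σ = 5 is
  a free replicate-noise parameter, documented rather than inferred.
  CO/OC loci switch at one stage drawn uniformly from stages 2..S.
  A `noiseless` mode makes the construction exactly separable for
  exact-recovery tests.
* **Bulk expression** (`simulate_bulk_signatures()`): log-normal baseline
  (meanlog = log 10, sdlog = 1) with signature genes multiplied by a
  per-stage effect.
* **Marker panel** (`simulate_marker_panel()`): true markers satisfy all
  four selection inequalities with ≥ 0.5 log2 margin; every non-marker
  violates at least one by the same margin, so exact recovery is
  guaranteed by construction, making the filter's test sharp.
* **Single cells** (`simulate_cell_matrix()`): negative-binomial counts
  (size = 2) with log-normal library factors, lineage markers elevated
  8-fold, `MT-` genes at 12x and `RPL/RPS` at 4x baseline so healthy
  cells sit near 3% pctMT, and a planted 5% QC-failing fraction split
  between collapsed-library and high-mitochondrial modes. Planted
  proportions use largest-remainder allocation, so class sizes are exact
  and recovery assertions need no multinomial slack.
* **Temporal patterns** (`simulate_temporal_patterns()`): six canonical,
  pairwise-distinct stage shapes (up, down, early/late transient, U,
  inverted-U) with Gaussian log2 jitter.

None of the generators emulate read-level data, doublets, ambient RNA,
batch effects, gene-length biases, or correlated gene modules beyond the
planted structure. Passing recovery tests therefore demonstrates that the
pipeline's logic is correct under its stated model — not that the
thresholds would reproduce on any particular real dataset. In particular,
the published genome-wide RPKM threshold of 14.22 at 1% FDR depends on
the deposited accession data and is documented here as the reference
procedure output, not reproduced.

## Problem sizes and numerical choices

The test suite and the acceptance script run the pipeline at sizes chosen
to exercise every rule while keeping runs quick on a laptop: 2000 regions
x 10 samples for accessibility (10 seeds), 500-region shuffles (10
seeds), 2000 cells x 4000 genes for the single-cell endpoint (5 seeds),
300-gene planted-pattern clustering, and 100 random peak/background pairs
(plus one 10^4-entry pair) for the threshold oracle. Determinism is
end-to-end: every stochastic function takes a seed, RNG state is
restored after use (`withr::with_seed`), ties break lexicographically,
and the pipeline manifest records MD5 digests so identical seed + config
reproduce identical files.

Degenerate inputs fail loudly rather than silently: inseparable
peak/background distributions, empty retained gene sets, fewer genes than
clusters, unplaceable background regions, zero library sizes, and
unstaged samples all raise errors naming the offending object.
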